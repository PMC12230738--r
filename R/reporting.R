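## Tabular outputs, summaries, coverage tracks and library-QC utilities.

#' Annotated sgRNA library table
#'
#' The tabular artifact of the design step: a core table of guide records
#' (identifier, protospacer, PAM, 1-based genomic position, strand, source
#' label, library type, off/on-target columns) plus one annotation block per
#' base editor.
#'
#' @slot core `data.frame` of core guide columns; `guide_id` unique.
#' @slot annotations Named list of per-editor annotation `data.frame`s.
#' @slot libraryType `"target"`, `"positive"` or `"negative"`.
#' @export
setClass("LibraryTable",
  representation(core = "data.frame", annotations = "list",
                 libraryType = "character"))

setValidity("LibraryTable", function(object) {
  if (nrow(object@core) && anyDuplicated(object@core$guide_id)) {
    return("guide_id must be unique within a library table")
  }
  if (!(object@libraryType %in% c("target", "positive", "negative"))) {
    return("libraryType must be target/positive/negative")
  }
  for (blk in object@annotations) {
    if (!all(blk$guide_id %in% object@core$guide_id)) {
      return("annotation block references unknown guide_id")
    }
  }
  TRUE
})

#' Construct a LibraryTable
#'
#' @param core Core guide `data.frame`.
#' @param annotations Named list of per-editor annotation blocks.
#' @param libraryType Library type string.
#' @export
LibraryTable <- function(core, annotations = list(), libraryType = "target") {
  new("LibraryTable", core = core, annotations = annotations,
      libraryType = libraryType)
}

setMethod("show", "LibraryTable", function(object) {
  cat("LibraryTable (", object@libraryType, "): ", nrow(object@core),
      " sgRNA(s), ", length(object@annotations),
      " editor annotation block(s)\n", sep = "")
})

#' @describeIn LibraryTable Core table accessor.
#' @param x A `LibraryTable`.
#' @export
libraryCore <- function(x) x@core

#' @describeIn LibraryTable Annotation blocks accessor.
#' @export
libraryAnnotations <- function(x) x@annotations

#' @describeIn LibraryTable Library type accessor.
#' @export
libraryType <- function(x) x@libraryType

.LIBRARY_FILES <- c(target = "Target_Library",
                    positive = "Positive_Control_Library",
                    negative = "Negative_Control_Library")

#' Write library tables to disk
#'
#' One CSV bundle per library type, using the standard base names
#' (`Target_Library`, `Positive_Control_Library`,
#' `Negative_Control_Library`): the core table as `<base>.csv` and one
#' annotation file per editor as `<base>_<editor>.csv`.
#'
#' @param tables List of [LibraryTable-class] objects.
#' @param outDir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
writeLibraryTables <- function(tables, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  paths <- character(0)
  for (tab in tables) {
    base <- .LIBRARY_FILES[[tab@libraryType]]
    p <- file.path(outDir, paste0(base, ".csv"))
    write.csv(tab@core, p, row.names = FALSE)
    paths <- c(paths, p)
    for (ed in names(tab@annotations)) {
      pe <- file.path(outDir, paste0(base, "_", ed, ".csv"))
      write.csv(tab@annotations[[ed]], pe, row.names = FALSE)
      paths <- c(paths, pe)
    }
  }
  invisible(paths)
}

#' Read a library table back from a CSV bundle
#'
#' @param outDir Directory written by [writeLibraryTables()].
#' @param libraryType Library type to read.
#' @param editors Character vector of editor names whose annotation blocks
#'   to load (default: all found on disk).
#' @return A [LibraryTable-class].
#' @export
readLibraryTable <- function(outDir, libraryType = "target", editors = NULL) {
  base <- .LIBRARY_FILES[[libraryType]]
  core <- read.csv(file.path(outDir, paste0(base, ".csv")),
                   stringsAsFactors = FALSE)
  if (is.null(editors)) {
    files <- list.files(outDir, pattern = paste0("^", base, "_.*\\.csv$"))
    editors <- sub("\\.csv$", "", sub(paste0("^", base, "_"), "", files))
  }
  ann <- lapply(editors, function(ed) {
    read.csv(file.path(outDir, paste0(base, "_", ed, ".csv")),
             stringsAsFactors = FALSE)
  })
  LibraryTable(core, setNames(ann, editors), libraryType)
}

#' Summarise a library: guides per gene and outcomes per editor
#'
#' @param tables List of [LibraryTable-class] objects.
#' @return List with `per_gene` (`data.frame`: source label, n sgRNAs) and
#'   `per_editor` (`data.frame`: library type, editor, outcome class, n).
#'   Outcome counts (including `no_edit`) partition each library per editor.
#' @export
summarizeLibrary <- function(tables) {
  perGene <- list()
  perEditor <- list()
  for (tab in tables) {
    if (nrow(tab@core)) {
      tg <- as.data.frame(table(tab@core$source_label),
                          stringsAsFactors = FALSE)
      names(tg) <- c("source_label", "n_sgrnas")
      tg$library_type <- tab@libraryType
      perGene[[length(perGene) + 1L]] <- tg
    }
    for (ed in names(tab@annotations)) {
      blk <- tab@annotations[[ed]]
      if (nrow(blk) == 0L) next
      tc <- as.data.frame(table(blk$aggregated_outcome),
                          stringsAsFactors = FALSE)
      names(tc) <- c("outcome", "n")
      tc$library_type <- tab@libraryType
      tc$editor <- ed
      perEditor[[length(perEditor) + 1L]] <- tc
    }
  }
  list(
    per_gene = if (length(perGene)) do.call(rbind, perGene)
               else data.frame(source_label = character(),
                               n_sgrnas = integer(),
                               library_type = character()),
    per_editor = if (length(perEditor)) do.call(rbind, perEditor)
                 else data.frame(outcome = character(), n = integer(),
                                 library_type = character(),
                                 editor = character()))
}

#' Gini index of an sgRNA count vector
#'
#' Standard Gini inequality coefficient,
#' `G = sum_i sum_j |x_i - x_j| / (2 n sum(x))`, computed via the sorted
#' form. 0 for perfectly uniform counts; values near 1 indicate a few guides
#' dominating the library. Operates on whatever count vector it is given
#' (raw or normalised).
#'
#' @param counts Non-negative numeric vector, not all zero.
#' @return Gini index in `[0, 1)`.
#' @examples
#' giniIndex(c(1, 0, 0, 0))  # 0.75
#' @export
giniIndex <- function(counts) {
  if (length(counts) == 0L) .stopf("counts must have length >= 1")
  if (any(counts < 0)) .stopf("counts must be non-negative")
  if (sum(counts) == 0) .stopf("counts must not be all zero")
  xs <- sort(counts)
  n <- length(xs)
  2 * sum(seq_len(n) * xs) / (n * sum(xs)) - (n + 1) / n
}

#' Per-slot read-count representation
#'
#' Descriptive summary of sgRNA read counts by oligomer slot position,
#' for diagnosing positional amplification bias in multiplexed libraries.
#'
#' @param countsBySlot `data.frame` with columns `slot` (integer, 1..k) and
#'   `count`.
#' @return `data.frame` with one row per slot: `slot`, `n`, `mean_count`,
#'   `median_count`.
#' @export
positionalRepresentation <- function(countsBySlot) {
  if (!all(c("slot", "count") %in% colnames(countsBySlot))) {
    .stopf("countsBySlot must have 'slot' and 'count' columns")
  }
  slots <- sort(unique(countsBySlot$slot))
  do.call(rbind, lapply(slots, function(s) {
    x <- countsBySlot$count[countsBySlot$slot == s]
    data.frame(slot = s, n = length(x), mean_count = mean(x),
               median_count = median(x))
  }))
}

#' Write sgRNA location and coverage tracks
#'
#' Static replacement for an interactive genome-browser report: a BED track
#' of guide locations and a BedGraph track of per-base sgRNA coverage.
#'
#' @param guides Guide `GRanges`.
#' @param outDir Output directory.
#' @param prefix File-name prefix (default `"sgrna"`).
#' @return Paths of the two written files, invisibly.
#' @export
writeCoverageTracks <- function(guides, outDir, prefix = "sgrna") {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  bed <- file.path(outDir, paste0(prefix, "_locations.bed"))
  md <- S4Vectors::mcols(guides)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(guides)),
                   start = GenomicRanges::start(guides) - 1L,
                   end = GenomicRanges::end(guides),
                   name = md$guide_id, score = 0L,
                   strand = as.character(GenomicRanges::strand(guides)))
  write.table(df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)

  bg <- file.path(outDir, paste0(prefix, "_coverage.bedgraph"))
  cov <- GenomicRanges::coverage(guides)
  lines <- character(0)
  for (ch in names(cov)) {
    r <- cov[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(1L, head(ends, -1L) + 1L)
    vals <- S4Vectors::runValue(r)
    keep <- vals > 0
    if (any(keep)) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%d", ch, starts[keep] - 1L,
                                ends[keep], vals[keep]))
    }
  }
  writeLines(lines, bg)
  invisible(c(bed, bg))
}
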