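## Genome + annotation loading, target resolution, BED output.

#' Load a genome assembly from FASTA
#'
#' Sequences are uppercased; duplicate headers and non-A/C/G/T/N characters
#' are rejected with an error naming the offending record.
#'
#' @param fastaPath Path to a FASTA file.
#' @param assemblyLabel Optional label; defaults to the file name.
#' @return A [GenomeAssembly-class].
#' @export
loadGenome <- function(fastaPath, assemblyLabel = basename(fastaPath)) {
  if (!file.exists(fastaPath)) .stopf("FASTA file not found: %s", fastaPath)
  ## readDNAStringSet silently drops invalid letters with a warning; catch it
  ## and name the offending record instead
  invalidCodes <- FALSE
  seqs <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(fastaPath),
             error = function(e) .stopf("malformed FASTA '%s': %s",
                                        fastaPath, conditionMessage(e))),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        invalidCodes <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (invalidCodes) {
    lines <- readLines(fastaPath)
    rec <- NA_character_
    for (ln in lines) {
      if (startsWith(ln, ">")) {
        rec <- sub("\\s.*$", "", sub("^>", "", ln))
      } else if (grepl("[^ACGTNacgtn[:space:]]", ln)) {
        .stopf("record '%s' contains characters outside A/C/G/T/N", rec)
      }
    }
    .stopf("FASTA '%s' contains invalid sequence characters", fastaPath)
  }
  ## keep only the first word of each header, as aligners do
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    .stopf("duplicate FASTA header(s): %s",
           paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = FALSE)
  allowed <- c("A", "C", "G", "T", "N", "a", "c", "g", "t", "n")
  badCols <- colnames(freq)[!(colnames(freq) %in% allowed)]
  badRow <- which(rowSums(freq[, badCols, drop = FALSE]) > 0)
  if (length(badRow)) {
    .stopf("record '%s' contains characters outside A/C/G/T/N",
           names(seqs)[badRow[1]])
  }
  GenomeAssembly(setNames(toupper(as.character(seqs)), names(seqs)),
                 assemblyLabel)
}

#' Load transcript models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features into one [TranscriptModel-class] per
#' mRNA and validates each model against the genome: exons sorted and
#' non-overlapping, within chromosome bounds; CDS contained in exons; CDS
#' length a multiple of 3. The canonical isoform is read from an
#' `Ensembl_canonical`-style `tag` attribute when present; otherwise the
#' transcript with the longest CDS per gene (ties broken by lexicographic
#' transcript id) is flagged canonical.
#'
#' @param gff3Path Path to a GFF3 file.
#' @param genome A [GenomeAssembly-class] used for bounds checking.
#' @return Named list of [TranscriptModel-class] objects (by transcript id).
#' @export
loadAnnotation <- function(gff3Path, genome) {
  if (!file.exists(gff3Path)) .stopf("GFF3 file not found: %s", gff3Path)
  gr <- rtracklayer::import(gff3Path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  lens <- chromLengths(genome)

  mrnaIdx <- which(type %in% c("mRNA", "transcript"))
  if (length(mrnaIdx) == 0L) .stopf("no mRNA/transcript features in %s", gff3Path)

  geneName <- function(i) {
    nm <- md$Name[i]
    if (!is.null(nm) && !is.na(nm) && nzchar(nm)) return(as.character(nm))
    as.character(md$ID[i])
  }
  ## map gene ID -> gene name
  geneIdx <- which(type == "gene")
  geneNames <- setNames(vapply(geneIdx, geneName, ""),
                        as.character(md$ID[geneIdx]))

  parentOf <- function(i) {
    p <- md$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[1])
  }

  models <- list()
  for (i in mrnaIdx) {
    txId <- as.character(md$ID[i])
    chrom <- as.character(GenomicRanges::seqnames(gr))[i]
    if (!(chrom %in% names(lens))) {
      .stopf("transcript %s on unknown chromosome %s", txId, chrom)
    }
    strand <- as.character(GenomicRanges::strand(gr))[i]
    kids <- which(vapply(seq_along(gr), function(j) {
      p <- md$Parent[[j]]
      length(p) > 0L && txId %in% as.character(p)
    }, logical(1)))
    exIdx <- kids[type[kids] == "exon"]
    cdsIdx <- kids[type[kids] == "CDS"]
    if (length(exIdx) == 0L) .stopf("transcript %s has no exons", txId)
    exons <- IRanges::IRanges(GenomicRanges::start(gr)[exIdx],
                              GenomicRanges::end(gr)[exIdx])
    cds <- if (length(cdsIdx)) {
      IRanges::IRanges(GenomicRanges::start(gr)[cdsIdx],
                       GenomicRanges::end(gr)[cdsIdx])
    } else IRanges::IRanges()
    if (max(IRanges::end(exons)) > lens[chrom] || min(IRanges::start(exons)) < 1L) {
      .stopf("transcript %s extends beyond chromosome %s bounds", txId, chrom)
    }
    gid <- parentOf(i)
    gname <- if (!is.na(gid) && gid %in% names(geneNames)) geneNames[[gid]]
             else geneName(i)
    canonical <- FALSE
    if ("tag" %in% colnames(md)) {
      tg <- md$tag[i]
      tagChr <- if (is(tg, "List") || is.list(md$tag)) {
        as.character(unlist(md$tag[i]))
      } else as.character(tg)
      canonical <- any(grepl("canonical", tagChr, ignore.case = TRUE))
    }
    models[[txId]] <- TranscriptModel(txId, gname, chrom, strand,
                                      exons, cds, isCanonical = canonical)
  }

  ## canonical fallback: longest CDS per gene, ties by lexicographic tx id
  byGene <- split(names(models),
                  vapply(models, function(m) m@geneName, ""))
  for (g in names(byGene)) {
    ids <- byGene[[g]]
    if (any(vapply(models[ids], function(m) m@isCanonical, TRUE))) next
    w <- vapply(models[ids], function(m) sum(IRanges::width(m@cds)), 0)
    pick <- ids[order(-w, ids)][1]
    models[[pick]]@isCanonical <- TRUE
  }
  models
}

#' Resolve target entries into non-overlapping genomic regions
#'
#' Entries are official gene names present in `annotation`, or region strings
#' `"chrom:start-end"` (1-based inclusive). Gene entries resolve to the union
#' of CDS intervals across isoforms (or the canonical isoform only); each
#' interval is extended by `flankNt` on each side, merged per entry, clipped
#' to chromosome bounds, and trimmed against the blacklist. Overlapping
#' regions from different entries are an error (they would duplicate sgRNAs).
#'
#' @param entries Character vector of gene names and/or region strings.
#' @param annotation Named list of [TranscriptModel-class] (gene entries may
#'   be omitted by passing `list()` when only region strings are used).
#' @param genome A [GenomeAssembly-class].
#' @param flankNt Non-negative flank added on each side of every interval.
#' @param canonicalOnly Use only canonical isoforms for gene entries.
#' @param blacklist Optional `GRanges` of excluded intervals (e.g. an
#'   ENCODE-style blacklist read from BED); overlaps are trimmed away.
#' @param maxTotalSpanNt Cap on the summed width of all resolved regions
#'   (default 1.5 Mb).
#' @param origin Origin tag recorded on region entries resolved from genes
#'   (`"gene_cds"`) is set automatically; this argument sets the tag used for
#'   `control_locus` design runs (default `"user_region"` for region strings).
#' @return A `GRanges` with metadata columns `label` and `origin`.
#' @export
resolveTargets <- function(entries, annotation, genome, flankNt = 0L,
                           canonicalOnly = FALSE, blacklist = NULL,
                           maxTotalSpanNt = 1500000L,
                           origin = "user_region") {
  if (flankNt < 0L) .stopf("flankNt must be >= 0")
  lens <- chromLengths(genome)
  geneOf <- vapply(annotation, function(m) m@geneName, "")

  perEntry <- list()
  for (entry in entries) {
    reg <- .parseRegionString(entry)
    if (!is.null(reg)) {
      if (!(reg$chrom %in% names(lens))) {
        .stopf("region '%s': unknown chromosome %s", entry, reg$chrom)
      }
      if (reg$start > reg$end) .stopf("region '%s': start > end", entry)
      if (reg$end > lens[reg$chrom]) {
        .stopf("region '%s' extends beyond chromosome end (%d)",
               entry, lens[reg$chrom])
      }
      gr <- GenomicRanges::GRanges(reg$chrom,
              IRanges::IRanges(reg$start, reg$end))
      ori <- origin
    } else {
      txs <- annotation[geneOf == entry]
      if (length(txs) == 0L) .stopf("unknown gene name: %s", entry)
      if (canonicalOnly) {
        txs <- txs[vapply(txs, function(m) m@isCanonical, TRUE)]
      }
      cdsList <- lapply(txs, function(m) {
        GenomicRanges::GRanges(m@chrom, m@cds)
      })
      gr <- GenomicRanges::reduce(do.call(c, unname(cdsList)))
      ori <- "gene_cds"
    }
    ## flank, clip to bounds (clipping logged), merge per entry
    st <- GenomicRanges::start(gr) - flankNt
    en <- GenomicRanges::end(gr) + flankNt
    chr <- as.character(GenomicRanges::seqnames(gr))
    clipLo <- st < 1L
    clipHi <- en > lens[chr]
    if (any(clipLo | clipHi)) {
      message("entry '", entry, "': ", sum(clipLo | clipHi),
              " interval(s) clipped at chromosome bounds")
    }
    st <- pmax(st, 1L)
    en <- pmin(en, lens[chr])
    gr <- GenomicRanges::reduce(
      GenomicRanges::GRanges(chr, IRanges::IRanges(st, en)))
    S4Vectors::mcols(gr)$label <- entry
    S4Vectors::mcols(gr)$origin <- ori
    perEntry[[entry]] <- gr
  }
  if (length(perEntry) == 0L) {
    return(GenomicRanges::GRanges(label = character(), origin = character()))
  }

  ## cross-entry overlap check (prevents duplicate sgRNA design)
  for (i in seq_along(perEntry)) {
    for (j in seq_len(i - 1L)) {
      if (length(GenomicRanges::findOverlaps(perEntry[[i]], perEntry[[j]]))) {
        .stopf("resolved regions overlap between entries '%s' and '%s'",
               names(perEntry)[j], names(perEntry)[i])
      }
    }
  }

  ## blacklist trimming (partially overlapping regions are trimmed, not dropped)
  out <- list()
  for (entry in names(perEntry)) {
    gr <- perEntry[[entry]]
    if (!is.null(blacklist) && length(blacklist)) {
      kept <- GenomicRanges::setdiff(gr, blacklist, ignore.strand = TRUE)
      if (length(kept) == 0L) {
        .warnf("entry '%s' lies entirely within the blacklist; dropped", entry)
        next
      }
      if (sum(GenomicRanges::width(kept)) < sum(GenomicRanges::width(gr))) {
        message("entry '", entry, "': trimmed ",
                sum(GenomicRanges::width(gr)) - sum(GenomicRanges::width(kept)),
                " nt overlapping the blacklist")
      }
      S4Vectors::mcols(kept)$label <- entry
      S4Vectors::mcols(kept)$origin <- S4Vectors::mcols(gr)$origin[1]
      gr <- kept
    }
    out[[entry]] <- gr
  }
  if (length(out) == 0L) {
    return(GenomicRanges::GRanges(label = character(), origin = character()))
  }
  res <- do.call(c, unname(out))
  total <- sum(GenomicRanges::width(res))
  if (total > maxTotalSpanNt) {
    .stopf("total resolved span %d nt exceeds the cap of %d nt",
           total, maxTotalSpanNt)
  }
  res[order(as.character(GenomicRanges::seqnames(res)),
            GenomicRanges::start(res))]
}

#' Write target regions to BED
#'
#' Standard 0-based half-open BED; one line per region, name column = label.
#'
#' @param regions `GRanges` with a `label` metadata column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(regions, path) {
  if (length(regions) == 0L) {
    cat("", file = path)
    return(invisible(path))
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = GenomicRanges::start(regions) - 1L,
                   end = GenomicRanges::end(regions),
                   name = S4Vectors::mcols(regions)$label)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as GRanges
#'
#' Minimal 0-based half-open BED reader (first four columns).
#'
#' @param path BED file path.
#' @return `GRanges` with a `label` column.
#' @export
readBed <- function(path) {
  if (file.size(path) == 0) {
    return(GenomicRanges::GRanges(label = character()))
  }
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  S4Vectors::mcols(gr)$label <- if (ncol(df) >= 4) as.character(df[[4]])
                                else NA_character_
  gr
}
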