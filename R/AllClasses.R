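#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   subseq translate countPattern matchPattern readDNAStringSet
#'   writeXStringSet
#' @importFrom GenomicRanges GRanges start end width strand seqnames
#'   reduce findOverlaps countOverlaps setdiff coverage sort
#' @importFrom IRanges IRanges ranges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle
#'   runLength runValue
NULL

## ---------------------------------------------------------------------------
## GenomeAssembly: reference sequences every downstream stage reads
## ---------------------------------------------------------------------------

#' Reference genome assembly
#'
#' Thin wrapper around a [Biostrings::DNAStringSet] holding one entry per
#' chromosome, plus a free-text assembly label. Sequences are uppercased on
#' load and restricted to the A/C/G/T/N alphabet.
#'
#' @slot sequences A `DNAStringSet`, one entry per chromosome.
#' @slot assemblyLabel Free-text label for the assembly.
#' @export
setClass("GenomeAssembly",
  representation(sequences = "DNAStringSet", assemblyLabel = "character"))

setValidity("GenomeAssembly", function(object) {
  nms <- names(object@sequences)
  if (is.null(nms) || any(!nzchar(nms))) {
    return("all chromosomes must have non-empty names")
  }
  if (anyDuplicated(nms)) {
    return(paste0("duplicate chromosome name(s): ",
                  paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  freq <- Biostrings::alphabetFrequency(object@sequences, baseOnly = FALSE)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- colnames(freq)[colSums(freq) > 0 & !(colnames(freq) %in% allowed)]
  if (length(bad)) {
    return(paste0("sequences contain characters outside A/C/G/T/N: ",
                  paste(bad, collapse = ", ")))
  }
  TRUE
})

#' Construct a GenomeAssembly from named sequences
#'
#' @param sequences Named character vector or `DNAStringSet`; uppercased.
#' @param assemblyLabel Free-text label.
#' @return A [GenomeAssembly-class] object.
#' @examples
#' ga <- GenomeAssembly(c(chr1 = "acgtACGT"), "toy")
#' chromLengths(ga)
#' @export
GenomeAssembly <- function(sequences, assemblyLabel = "unnamed_assembly") {
  if (is.character(sequences)) {
    sequences <- DNAStringSet(toupper(sequences))
  } else {
    sequences <- DNAStringSet(toupper(as.character(sequences)))
  }
  new("GenomeAssembly", sequences = sequences, assemblyLabel = assemblyLabel)
}

setMethod("show", "GenomeAssembly", function(object) {
  cat("GenomeAssembly '", object@assemblyLabel, "': ",
      length(object@sequences), " chromosome(s), ",
      sum(Biostrings::width(object@sequences)), " nt total\n", sep = "")
})

#' @describeIn GenomeAssembly Chromosome lengths, named by chromosome.
#' @param genome A `GenomeAssembly`.
#' @export
chromLengths <- function(genome) {
  setNames(Biostrings::width(genome@sequences), names(genome@sequences))
}

#' @describeIn GenomeAssembly The underlying `DNAStringSet`.
#' @export
genomeSequences <- function(genome) genome@sequences

## Extract genome[chrom, start..end] (1-based closed), optionally revcomp
.genomeSubseq <- function(genome, chrom, start, end, strand = "+") {
  s <- genome@sequences[[chrom]]
  x <- Biostrings::subseq(s, start = start, end = end)
  if (strand == "-") x <- Biostrings::reverseComplement(x)
  as.character(x)
}

## ---------------------------------------------------------------------------
## TranscriptModel: exon/CDS structure of one transcript
## ---------------------------------------------------------------------------

#' Transcript model
#'
#' Exon and CDS structure of one mRNA. Intervals are stored as
#' 1-based closed [IRanges::IRanges] (the Bioconductor convention);
#' 0-based half-open coordinates appear only at the BED boundary.
#'
#' @slot transcriptId Transcript identifier.
#' @slot geneName Official gene name.
#' @slot chrom Chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons Sorted, non-overlapping exon intervals.
#' @slot cds CDS intervals, each contained in some exon; total width a
#'   multiple of 3 when non-empty.
#' @slot isCanonical Canonical-isoform flag.
#' @export
setClass("TranscriptModel",
  representation(transcriptId = "character", geneName = "character",
                 chrom = "character", strand = "character",
                 exons = "IRanges", cds = "IRanges",
                 isCanonical = "logical"))

setValidity("TranscriptModel", function(object) {
  ex <- object@exons
  if (length(ex) == 0L) return("transcript has no exons")
  if (!(object@strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  st <- IRanges::start(ex)
  if (is.unsorted(st, strictly = FALSE)) return("exons must be sorted by start")
  if (length(ex) > 1L &&
      any(IRanges::start(ex)[-1] <= IRanges::end(ex)[-length(ex)])) {
    return("exons must be non-overlapping")
  }
  cds <- object@cds
  if (length(cds)) {
    ov <- IRanges::findOverlaps(cds, ex, type = "within")
    if (length(unique(S4Vectors::queryHits(ov))) < length(cds)) {
      return(paste0("CDS interval outside exons in ", object@transcriptId))
    }
    if (sum(IRanges::width(cds)) %% 3L != 0L) {
      return(paste0("CDS length ", sum(IRanges::width(cds)),
                    " of ", object@transcriptId, " is not a multiple of 3"))
    }
  }
  TRUE
})

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneName,chrom,strand Identifiers and location.
#' @param exons,cds `IRanges` of exon and CDS intervals (1-based closed).
#' @param isCanonical Canonical flag.
#' @export
TranscriptModel <- function(transcriptId, geneName, chrom, strand,
                            exons, cds, isCanonical = FALSE) {
  exons <- exons[order(IRanges::start(exons))]
  cds <- cds[order(IRanges::start(cds))]
  new("TranscriptModel", transcriptId = transcriptId, geneName = geneName,
      chrom = chrom, strand = strand, exons = exons, cds = cds,
      isCanonical = isCanonical)
}

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel ", object@transcriptId, " (", object@geneName, ") ",
      object@chrom, ":", min(IRanges::start(object@exons)), "-",
      max(IRanges::end(object@exons)), " [", object@strand, "] ",
      length(object@exons), " exon(s), CDS ",
      sum(IRanges::width(object@cds)), " nt",
      if (object@isCanonical) " [canonical]" else "", "\n", sep = "")
})

#' Spliced CDS sequence of a transcript, 5'->3' on the coding strand
#'
#' @param genome A [GenomeAssembly-class].
#' @param tx A [TranscriptModel-class].
#' @return Character CDS sequence (empty string for non-coding transcripts).
#' @export
cdsSequence <- function(genome, tx) {
  if (length(tx@cds) == 0L) return("")
  pieces <- vapply(seq_along(tx@cds), function(i) {
    .genomeSubseq(genome, tx@chrom, IRanges::start(tx@cds)[i],
                  IRanges::end(tx@cds)[i], "+")
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (tx@strand == "-") s <- .revcomp(s)
  s
}

## ---------------------------------------------------------------------------
## CasVariant / BaseEditor: configuration records
## ---------------------------------------------------------------------------

#' Cas variant definition
#'
#' Parameterises PAM scanning. Only 3'-PAM (Cas9-family) architectures are
#' supported in this release; 5'-PAM variants are rejected.
#'
#' @slot name Variant name, e.g. `"SpCas9"`.
#' @slot pamPatterns IUPAC PAM patterns (equal length), e.g. `"NGG"`.
#' @slot pamSide Fixed to `"3prime"`.
#' @slot protospacerLength Protospacer length in nt (default 20).
#' @slot isSpCas9Family Gates CFD off-target filtering and on-target scoring.
#' @export
setClass("CasVariant",
  representation(name = "character", pamPatterns = "character",
                 pamSide = "character", protospacerLength = "integer",
                 isSpCas9Family = "logical"))

setValidity("CasVariant", function(object) {
  if (length(object@pamPatterns) == 0L) return("at least one PAM pattern required")
  if (object@pamSide != "3prime") {
    return("only 3'-PAM Cas variants are supported in this release")
  }
  chars <- unique(unlist(strsplit(object@pamPatterns, "")))
  if (!all(chars %in% names(.IUPAC))) {
    return("PAM patterns must use the IUPAC alphabet")
  }
  if (length(unique(nchar(object@pamPatterns))) != 1L) {
    return("all PAM patterns of a variant must have equal length")
  }
  if (object@protospacerLength < 1L) return("protospacerLength must be >= 1")
  TRUE
})

#' Construct a CasVariant
#'
#' @param name Variant name.
#' @param pamPatterns Character vector of IUPAC PAM patterns.
#' @param pamSide `"3prime"` (the only supported architecture).
#' @param protospacerLength Protospacer length (nt).
#' @param isSpCas9Family Whether CFD filtering and on-target scoring apply.
#' @examples
#' casVariant("SpG", c("NGG", "NGA", "NGC", "NGT"))
#' @export
casVariant <- function(name, pamPatterns, pamSide = "3prime",
                       protospacerLength = 20L, isSpCas9Family = TRUE) {
  new("CasVariant", name = name, pamPatterns = toupper(pamPatterns),
      pamSide = pamSide, protospacerLength = as.integer(protospacerLength),
      isSpCas9Family = isSpCas9Family)
}

#' Built-in Cas variant presets
#'
#' @param name One of `"SpCas9"` (NGG), `"SpG"` (NGG/NGA/NGC/NGT),
#'   `"SpRY"` (NNN).
#' @return A [CasVariant-class].
#' @export
casVariantPreset <- function(name = c("SpCas9", "SpG", "SpRY")) {
  name <- match.arg(name)
  switch(name,
    SpCas9 = casVariant("SpCas9", "NGG"),
    SpG    = casVariant("SpG", c("NGG", "NGA", "NGC", "NGT")),
    SpRY   = casVariant("SpRY", "NNN"))
}

setMethod("show", "CasVariant", function(object) {
  cat("CasVariant ", object@name, ": PAM {",
      paste(object@pamPatterns, collapse = ","), "} 3' of a ",
      object@protospacerLength, "-nt protospacer",
      if (object@isSpCas9Family) " [SpCas9 family]" else "", "\n", sep = "")
})

#' Base editor definition
#'
#' Window positions are 1-based protospacer positions counted from the
#' 5' (PAM-distal) end -- the standard base-editing convention (BE4 ~ 4-8).
#'
#' @slot name Editor name.
#' @slot windowStart,windowEnd Activity window (1-based protospacer positions).
#' @slot refBase Edited base on the protospacer strand (`"A"` or `"C"`).
#' @slot altBase Installed base.
#' @slot excludeGC If `TRUE`, a C immediately preceded by G on the
#'   protospacer strand is left unedited (APOBEC-1 GC-motif disfavouring).
#' @export
setClass("BaseEditor",
  representation(name = "character", windowStart = "integer",
                 windowEnd = "integer", refBase = "character",
                 altBase = "character", excludeGC = "logical"))

setValidity("BaseEditor", function(object) {
  if (object@windowStart < 1L || object@windowStart > object@windowEnd) {
    return("require 1 <= windowStart <= windowEnd")
  }
  if (!(object@refBase %in% c("A", "C"))) return("refBase must be A or C")
  if (object@refBase == object@altBase) return("refBase must differ from altBase")
  if (!(object@altBase %in% c("A", "C", "G", "T"))) {
    return("altBase must be one of A/C/G/T")
  }
  TRUE
})

#' Construct a BaseEditor
#'
#' @param name Editor name.
#' @param windowStart,windowEnd Activity window, 1-based protospacer
#'   positions from the PAM-distal 5' end.
#' @param refBase,altBase The substitution installed (protospacer strand).
#' @param excludeGC Skip Cs in GC motifs (CBEs only).
#' @examples
#' baseEditor("BE4", 4, 8, "C", "T", excludeGC = FALSE)
#' @export
baseEditor <- function(name, windowStart, windowEnd, refBase, altBase,
                       excludeGC = FALSE) {
  new("BaseEditor", name = name, windowStart = as.integer(windowStart),
      windowEnd = as.integer(windowEnd), refBase = toupper(refBase),
      altBase = toupper(altBase), excludeGC = excludeGC)
}

#' Built-in base editor presets
#'
#' @param name `"BE4"` (C>T, window 4-8) or `"ABE8e"` (A>G, window 4-8).
#' @return A [BaseEditor-class].
#' @export
baseEditorPreset <- function(name = c("BE4", "ABE8e")) {
  name <- match.arg(name)
  switch(name,
    BE4   = baseEditor("BE4", 4L, 8L, "C", "T", excludeGC = FALSE),
    ABE8e = baseEditor("ABE8e", 4L, 8L, "A", "G", excludeGC = FALSE))
}

setMethod("show", "BaseEditor", function(object) {
  cat("BaseEditor ", object@name, ": ", object@refBase, ">", object@altBase,
      " in window ", object@windowStart, "-", object@windowEnd,
      if (object@excludeGC) " (GC motifs excluded)" else "", "\n", sep = "")
})

#' Read Cas variant and base editor definitions from a YAML config
#'
#' The file may contain top-level keys `cas_variants` and `base_editors`,
#' each a list of records, e.g.
#' `{name: BE4, window: [4, 8], edit: "C>T", exclude_gc: false}` for editors
#' and `{name: SpG, pam_patterns: [NGG, NGA, NGC, NGT]}` for Cas variants.
#'
#' @param path YAML file path.
#' @return List with elements `casVariants` and `baseEditors`.
#' @export
readEditorConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cas <- lapply(cfg$cas_variants, function(x) {
    casVariant(x$name, unlist(x$pam_patterns),
               protospacerLength = x$protospacer_length %||% 20L,
               isSpCas9Family = x$is_spcas9_family %||% TRUE)
  })
  eds <- lapply(cfg$base_editors, function(x) {
    parts <- strsplit(toupper(x$edit), ">")[[1]]
    baseEditor(x$name, x$window[1], x$window[2], parts[1], parts[2],
               excludeGC = isTRUE(x$exclude_gc))
  })
  list(casVariants = setNames(cas, vapply(cas, function(v) v@name, "")),
       baseEditors = setNames(eds, vapply(eds, function(e) e@name, "")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
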