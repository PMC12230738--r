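## Protospacer scanning against a Cas variant's PAM set.

## Enumerate every full-length protospacer+PAM site on one chromosome,
## both strands. Returns a data.frame with 1-based closed protospacer
## coordinates, protospacer/PAM sequences in protospacer-strand orientation.
.pamSitesChrom <- function(genome, chrom, cas) {
  L <- cas@protospacerLength
  P <- nchar(cas@pamPatterns[1])
  seqChr <- as.character(genome@sequences[[chrom]])
  n <- nchar(seqChr)
  if (n < L + P) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      protospacer = character(), pam = character()))
  }

  scanStrand <- function(s) {
    ## s is the protospacer-strand sequence (chrom or its revcomp);
    ## protospacer occupies [i, i+L-1], PAM [i+L, i+L+P-1]
    starts <- seq_len(nchar(s) - L - P + 1L)
    pams <- substring(s, starts + L, starts + L + P - 1L)
    hit <- .matchesAnyPam(pams, cas@pamPatterns)
    starts <- starts[hit]
    pams <- pams[hit]
    if (length(starts) == 0L) {
      return(list(starts = integer(0), protos = character(0),
                  pams = character(0)))
    }
    protos <- substring(s, starts, starts + L - 1L)
    keep <- !grepl("N", protos, fixed = TRUE)
    list(starts = starts[keep], protos = protos[keep], pams = pams[keep])
  }

  fwd <- scanStrand(seqChr)
  rev <- scanStrand(.revcomp(seqChr))
  ## map reverse-strand local start i (on revcomp) back to genomic coords:
  ## protospacer occupies genomic [n - (i+L-1) + 1, n - i + 1]
  revStartG <- n - (rev$starts + L - 1L) + 1L

  nTot <- length(fwd$starts) + length(rev$starts)
  df <- data.frame(
    chrom = rep(chrom, nTot),
    strand = c(rep("+", length(fwd$starts)), rep("-", length(rev$starts))),
    start = c(fwd$starts, revStartG),
    end = c(fwd$starts + L - 1L, revStartG + L - 1L),
    protospacer = c(fwd$protos, rev$protos),
    pam = c(fwd$pams, rev$pams),
    stringsAsFactors = FALSE
  )
  df[order(df$start, df$strand), , drop = FALSE]
}

## Genome-wide PAM site table (used by scanning and off-target enumeration).
.pamSites <- function(genome, cas) {
  do.call(rbind, lapply(names(genome@sequences), function(ch) {
    .pamSitesChrom(genome, ch, cas)
  }))
}

.sitesToGuides <- function(df, sourceLabel, libraryType) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$guide_id <- .guideId(df$chrom, df$start, df$end,
                                            df$strand)
  S4Vectors::mcols(gr)$protospacer <- df$protospacer
  S4Vectors::mcols(gr)$pam <- df$pam
  S4Vectors::mcols(gr)$source_label <- rep(sourceLabel, nrow(df))
  S4Vectors::mcols(gr)$library_type <- rep(libraryType, nrow(df))
  gr
}

#' Scan a target region for sgRNAs
#'
#' Emits one guide for every position on either strand where a full-length
#' protospacer with a 3' PAM matching one of the Cas variant's patterns fits
#' inside the chromosome and the protospacer overlaps the region by at least
#' 1 nt. Protospacers containing N are dropped. Output is sorted by
#' (chrom, start, strand) and carries stable coordinate-derived guide ids
#' (`"chrom:start-end:strand"`, 0-based half-open).
#'
#' @param region A single-element `GRanges` target region with a `label`
#'   metadata column (as produced by [resolveTargets()]).
#' @param genome A [GenomeAssembly-class].
#' @param cas A [CasVariant-class].
#' @param libraryType One of `"target"`, `"positive"`, `"negative"`.
#' @return A `GRanges` of protospacer intervals with metadata columns
#'   `guide_id`, `protospacer`, `pam`, `source_label`, `library_type`.
#' @examples
#' ga <- GenomeAssembly(c(chr1 = paste0(strrep("A", 20), "TGG", "AAAA")))
#' region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 27))
#' S4Vectors::mcols(region)$label <- "toy"
#' scanGuides(region, ga, casVariantPreset("SpCas9"))
#' @export
scanGuides <- function(region, genome, cas, libraryType = "target") {
  chrom <- as.character(GenomicRanges::seqnames(region))
  lens <- chromLengths(genome)
  if (!all(chrom %in% names(lens))) {
    .stopf("region chromosome not in genome: %s",
           paste(base::setdiff(chrom, names(lens)), collapse = ", "))
  }
  if (any(GenomicRanges::end(region) > lens[chrom]) ||
      any(GenomicRanges::start(region) < 1L)) {
    .stopf("region outside genome bounds")
  }
  out <- list()
  for (i in seq_along(region)) {
    ch <- chrom[i]
    sites <- .pamSitesChrom(genome, ch, cas)
    keep <- sites$end >= GenomicRanges::start(region)[i] &
            sites$start <= GenomicRanges::end(region)[i]
    lbl <- S4Vectors::mcols(region)$label
    lbl <- if (is.null(lbl)) NA_character_ else lbl[i]
    out[[i]] <- .sitesToGuides(sites[keep, , drop = FALSE], lbl, libraryType)
  }
  res <- do.call(c, out)
  unique(res)
}

#' Scan a set of resolved target regions
#'
#' Convenience wrapper applying [scanGuides()] to each region of a
#' [resolveTargets()] result and concatenating the output.
#'
#' @inheritParams scanGuides
#' @param regions `GRanges` of target regions with `label` column.
#' @return A `GRanges` of guides (see [scanGuides()]).
#' @export
scanGuideSet <- function(regions, genome, cas, libraryType = "target") {
  if (length(regions) == 0L) {
    return(scanGuides(regions, genome, cas, libraryType))
  }
  out <- lapply(seq_along(regions), function(i) {
    scanGuides(regions[i], genome, cas, libraryType)
  })
  res <- do.call(c, out)
  ## a protospacer may overlap two nearby intervals of the same entry
  ## (e.g. flanked exons separated by a short intron): keep one copy
  res[!duplicated(S4Vectors::mcols(res)$guide_id)]
}

#' Convert a guide GRanges to the core library data.frame
#'
#' Produces the user-facing table columns with 1-based inclusive genomic
#' coordinates (the spreadsheet convention).
#'
#' @param guides Guide `GRanges` from [scanGuides()].
#' @return `data.frame` with one row per guide.
#' @export
guidesToDataFrame <- function(guides) {
  md <- S4Vectors::mcols(guides)
  data.frame(
    guide_id = md$guide_id,
    protospacer = md$protospacer,
    pam = md$pam,
    chrom = as.character(GenomicRanges::seqnames(guides)),
    start = GenomicRanges::start(guides),
    end = GenomicRanges::end(guides),
    strand = as.character(GenomicRanges::strand(guides)),
    source_label = md$source_label,
    library_type = md$library_type,
    stringsAsFactors = FALSE
  )
}
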