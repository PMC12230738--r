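## Off-target enumeration (exhaustive scan), variant-adjusted CFD scoring,
## threshold filtering, and the pluggable on-target scorer.

#' Mismatch penalty matrix for CFD scoring
#'
#' Per-position, per-base-pair mismatch factors plus the variant-adjusted PAM
#' factor rule: any PAM matching one of the Cas variant's patterns scores
#' 1.0 (100% cutting efficiency), every other PAM scores 0.0. This is the
#' conservative adjustment that extends the SpCas9 CFD scheme to engineered
#' variants with relaxed PAMs (e.g. under SpG, NGG/NGA/NGC/NGT all score 1).
#'
#' @slot penalties Numeric array `[position, guide_base, offtarget_base]`;
#'   matched bases have factor 1; all factors in `[0, 1]`.
#' @slot pamPatterns IUPAC patterns scoring factor 1.
#' @slot version Table version string.
#' @export
setClass("MismatchPenaltyMatrix",
  representation(penalties = "array", pamPatterns = "character",
                 version = "character"))

setValidity("MismatchPenaltyMatrix", function(object) {
  p <- object@penalties
  if (length(dim(p)) != 3L) return("penalties must be a 3-d array")
  if (any(p < 0 | p > 1)) return("all factors must lie in [0, 1]")
  for (b in c("A", "C", "G", "T")) {
    if (any(p[, b, b] != 1)) return("matched bases must have factor 1")
  }
  TRUE
})

#' Build the mismatch penalty matrix for a Cas variant
#'
#' Loads the shipped synthetic mismatch-penalty table (see
#' `inst/extdata/cfd_mismatch_penalties_synthetic.tsv`; a structural
#' stand-in for the published CFD factors, documented in the file header)
#' and derives the PAM factor vector from the variant's PAM patterns.
#'
#' @param cas A [CasVariant-class].
#' @param tablePath Optional path to an alternative penalty TSV with columns
#'   `position`, `guide_base`, `offtarget_base`, `factor` (mismatches only;
#'   matches are filled with 1).
#' @return A [MismatchPenaltyMatrix-class].
#' @examples
#' m <- mismatchPenaltyMatrix(casVariantPreset("SpG"))
#' pamFactor(m, "TGA")  # 1: NGA is an allowed SpG PAM
#' pamFactor(m, "TAA")  # 0: not in the allowed set
#' @export
mismatchPenaltyMatrix <- function(cas, tablePath = NULL) {
  if (is.null(tablePath)) {
    tablePath <- system.file("extdata", "cfd_mismatch_penalties_synthetic.tsv",
                             package = "beTiler", mustWork = TRUE)
  }
  tab <- read.delim(tablePath, comment.char = "#", stringsAsFactors = FALSE)
  L <- cas@protospacerLength
  bases <- c("A", "C", "G", "T")
  arr <- array(NA_real_, dim = c(L, 4, 4),
               dimnames = list(NULL, bases, bases))
  for (b in bases) arr[, b, b] <- 1
  tab <- tab[tab$position <= L, , drop = FALSE]
  idx <- cbind(tab$position, match(tab$guide_base, bases),
               match(tab$offtarget_base, bases))
  arr[idx] <- tab$factor
  if (anyNA(arr)) {
    .stopf("penalty table is not total over positions 1..%d x {A,C,G,T}^2", L)
  }
  new("MismatchPenaltyMatrix", penalties = arr,
      pamPatterns = cas@pamPatterns, version = "synthetic-0.1.0")
}

setMethod("show", "MismatchPenaltyMatrix", function(object) {
  cat("MismatchPenaltyMatrix (", object@version, "): ",
      dim(object@penalties)[1], " positions; PAM factor 1 for {",
      paste(object@pamPatterns, collapse = ","), "}, 0 otherwise\n", sep = "")
})

#' @describeIn mismatchPenaltyMatrix Variant-adjusted PAM factor: 1 for PAMs
#'   matching an allowed pattern, 0 for all others. Vectorised over `pam`.
#' @param matrix A [MismatchPenaltyMatrix-class].
#' @param pam Character vector of PAM sequences.
#' @export
pamFactor <- function(matrix, pam) {
  as.numeric(.matchesAnyPam(pam, matrix@pamPatterns))
}

#' Cutting Frequency Determination (CFD) score of an off-target site
#'
#' Product of per-position mismatch factors (positions counted 1-based from
#' the 5', PAM-distal end of the protospacer) times the variant-adjusted PAM
#' factor. A perfect match with an allowed PAM scores exactly 1; any site
#' with a disallowed PAM scores 0. Ambiguous (N) bases never match: a site
#' containing N scores 0.
#'
#' @param protospacer Guide protospacer sequence (5'->3').
#' @param siteSequence Off-target site sequence, protospacer-strand
#'   orientation, same length.
#' @param pam PAM sequence at the site.
#' @param matrix A [MismatchPenaltyMatrix-class].
#' @return Numeric score in `[0, 1]`.
#' @export
cfdScore <- function(protospacer, siteSequence, pam, matrix) {
  if (nchar(protospacer) != nchar(siteSequence)) {
    .stopf("protospacer and site sequence lengths differ")
  }
  g <- strsplit(protospacer, "")[[1]]
  o <- strsplit(siteSequence, "")[[1]]
  if (any(g == "N") || any(o == "N")) return(0)
  bases <- c("A", "C", "G", "T")
  gi <- match(g, bases)
  oi <- match(o, bases)
  if (anyNA(gi) || anyNA(oi)) {
    .stopf("unknown base pair key: matrix is total over A/C/G/T only")
  }
  prod(matrix@penalties[cbind(seq_along(g), gi, oi)]) * pamFactor(matrix, pam)
}

#' Enumerate genome-wide off-target sites of a guide
#'
#' Exhaustive scan: every genomic window on either strand carrying an allowed
#' PAM and lying within `maxMismatches` Hamming distance of the protospacer
#' is returned, including the on-target site itself. Sites with disallowed
#' PAMs are excluded at enumeration -- equivalent to the 0% PAM factor rule.
#' Exact at fixture scale; not intended for full mammalian genomes.
#'
#' @param guide Single-element guide `GRanges` (from [scanGuides()]).
#' @param genome A [GenomeAssembly-class].
#' @param cas A [CasVariant-class].
#' @param maxMismatches Mismatch budget (0-4).
#' @param matrix Optional [MismatchPenaltyMatrix-class]; built from `cas`
#'   when omitted.
#' @param sites Optional precomputed genome-wide PAM site table (internal
#'   reuse across many guides).
#' @return `data.frame` with columns `chrom`, `strand`, `start`, `end`
#'   (1-based closed site interval), `site_sequence`, `pam`, `n_mismatches`,
#'   `mismatch_positions` (comma-separated), `cfd`, `is_on_target`.
#' @export
enumerateOfftargets <- function(guide, genome, cas, maxMismatches = 3L,
                                matrix = NULL, sites = NULL) {
  if (maxMismatches > 4L) .stopf("maxMismatches must be <= 4")
  if (is.null(matrix)) matrix <- mismatchPenaltyMatrix(cas)
  if (is.null(sites)) sites <- .pamSites(genome, cas)
  proto <- S4Vectors::mcols(guide)$protospacer
  gchars <- strsplit(proto, "")[[1]]

  m <- .charMatrix(sites$protospacer)
  mm <- rowSums(sweep(m, 2, gchars, FUN = "!="))
  keep <- mm <= maxMismatches
  hits <- sites[keep, , drop = FALSE]
  mmKeep <- mm[keep]
  mk <- m[keep, , drop = FALSE]

  mmPos <- vapply(seq_len(nrow(hits)), function(i) {
    paste(which(mk[i, ] != gchars), collapse = ",")
  }, character(1))
  cfd <- vapply(seq_len(nrow(hits)), function(i) {
    cfdScore(proto, hits$protospacer[i], hits$pam[i], matrix)
  }, numeric(1))

  onTarget <- hits$chrom == as.character(GenomicRanges::seqnames(guide)) &
    hits$start == GenomicRanges::start(guide) &
    hits$end == GenomicRanges::end(guide) &
    hits$strand == as.character(GenomicRanges::strand(guide))

  data.frame(chrom = hits$chrom, strand = hits$strand,
             start = hits$start, end = hits$end,
             site_sequence = hits$protospacer, pam = hits$pam,
             n_mismatches = mmKeep, mismatch_positions = mmPos,
             cfd = cfd, is_on_target = onTarget,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter a guide set on off-target thresholds
#'
#' A guide is removed iff its count of off-target hits with
#' `cfd >= cfdThreshold` -- excluding the on-target site, identified by exact
#' (chrom, interval, strand) identity -- exceeds `maxOfftargets`. Only
#' SpCas9-family variants are filtered (the CFD scheme was developed for
#' SpCas9); other variants pass through unfiltered with a warning.
#'
#' @param guides Guide `GRanges`.
#' @param genome A [GenomeAssembly-class].
#' @param cas A [CasVariant-class].
#' @param maxOfftargets Maximum allowed scoring off-targets per guide.
#' @param cfdThreshold CFD score at or above which a hit counts.
#' @param maxMismatches Mismatch budget for enumeration.
#' @return List with `kept` and `removed` guide `GRanges` (both annotated
#'   with `n_offtargets` and `max_offtarget_cfd` metadata columns) and a
#'   `reasons` data.frame logging each removal.
#' @export
filterByOfftargets <- function(guides, genome, cas, maxOfftargets = 0L,
                               cfdThreshold = 0.2, maxMismatches = 3L) {
  if (!cas@isSpCas9Family) {
    .warnf("off-target filtering is only available for SpCas9 variants; %s passes through unfiltered",
           cas@name)
    S4Vectors::mcols(guides)$n_offtargets <- NA_integer_
    S4Vectors::mcols(guides)$max_offtarget_cfd <- NA_real_
    return(list(kept = guides, removed = guides[0],
                reasons = data.frame(guide_id = character(),
                                     reason = character())))
  }
  matrix <- mismatchPenaltyMatrix(cas)
  sites <- .pamSites(genome, cas)
  nOff <- integer(length(guides))
  maxCfd <- numeric(length(guides))
  for (i in seq_along(guides)) {
    hits <- enumerateOfftargets(guides[i], genome, cas, maxMismatches,
                                matrix = matrix, sites = sites)
    off <- hits[!hits$is_on_target, , drop = FALSE]
    scoring <- off[off$cfd >= cfdThreshold, , drop = FALSE]
    nOff[i] <- nrow(scoring)
    maxCfd[i] <- if (nrow(off)) max(off$cfd) else 0
  }
  S4Vectors::mcols(guides)$n_offtargets <- nOff
  S4Vectors::mcols(guides)$max_offtarget_cfd <- maxCfd
  removeIdx <- nOff > maxOfftargets
  reasons <- data.frame(
    guide_id = S4Vectors::mcols(guides)$guide_id[removeIdx],
    reason = sprintf("%d off-target site(s) with CFD >= %g (max allowed %d)",
                     nOff[removeIdx], cfdThreshold, maxOfftargets),
    stringsAsFactors = FALSE)
  list(kept = guides[!removeIdx], removed = guides[removeIdx],
       reasons = reasons)
}

#' On-target efficiency score (pluggable)
#'
#' Trained on-target models (e.g. Rule Set 3) are not bundled; the default
#' scorer is a deterministic, explicitly labelled surrogate mapping the
#' 30-nt context (4 nt upstream + 20 nt protospacer + 3 nt PAM + 3 nt
#' downstream, protospacer-strand orientation) to `[0, 1]` via a Gaussian
#' GC-content preference centred at 55% with a small bonus for a G at
#' protospacer position 20. Any user function `function(context) -> numeric`
#' can be plugged in; its output passes through unchanged. `scorer = NULL`
#' yields an empty (NA) score column.
#'
#' @param guides Guide `GRanges`.
#' @param genome A [GenomeAssembly-class].
#' @param scorer `"surrogate"` (default), `NULL`, or a function of the 30-nt
#'   context string.
#' @return `guides` with numeric metadata columns `on_target_score` and
#'   `on_target_method`. Guides whose context is clipped at a chromosome end
#'   get `NA` with a warning.
#' @export
onTargetScore <- function(guides, genome, scorer = "surrogate") {
  n <- length(guides)
  score <- rep(NA_real_, n)
  method <- if (is.null(scorer)) "none"
            else if (is.function(scorer)) "external" else "surrogate"
  if (!is.null(scorer)) {
    lens <- chromLengths(genome)
    clipped <- 0L
    for (i in seq_len(n)) {
      ch <- as.character(GenomicRanges::seqnames(guides))[i]
      st <- GenomicRanges::start(guides)[i]
      en <- GenomicRanges::end(guides)[i]
      sd <- as.character(GenomicRanges::strand(guides))[i]
      if (sd == "+") { lo <- st - 4L; hi <- en + 6L }
      else { lo <- st - 6L; hi <- en + 4L }
      if (lo < 1L || hi > lens[ch]) { clipped <- clipped + 1L; next }
      ctx <- .genomeSubseq(genome, ch, lo, hi, sd)
      score[i] <- if (is.function(scorer)) scorer(ctx)
                  else .surrogateOnTarget(ctx)
    }
    if (clipped > 0L) {
      .warnf("%d guide(s) lack the full 30-nt context (chromosome end); score set to NA",
             clipped)
    }
  }
  S4Vectors::mcols(guides)$on_target_score <- score
  S4Vectors::mcols(guides)$on_target_method <- method
  guides
}

## Documented surrogate heuristic: Gaussian GC preference (optimum 0.55,
## sd 0.15) over the protospacer, +10% bonus for G at position 20, clipped
## to [0, 1]. Deterministic by construction.
.surrogateOnTarget <- function(context) {
  proto <- substring(context, 5L, 24L)
  b <- strsplit(proto, "")[[1]]
  gc <- mean(b %in% c("G", "C"))
  s <- exp(-((gc - 0.55)^2) / (2 * 0.15^2)) * (0.9 + 0.1 * (b[20] == "G"))
  max(0, min(1, s))
}
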