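## Internal helpers: coordinate conversions, IUPAC matching, seeded RNG.

#' @import methods
#' @importFrom stats median setNames
#' @importFrom utils read.delim write.table write.csv read.csv head
NULL

## IUPAC code -> character class of concrete bases
.IUPAC <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

## Does a concrete DNA string match an IUPAC pattern of the same length?
## Vectorised over `seqs`. Ambiguous bases (N) in `seqs` never match.
.matchesIupac <- function(seqs, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  cls <- .IUPAC[pat]
  if (anyNA(cls)) {
    stop("invalid IUPAC code in pattern '", pattern, "'", call. = FALSE)
  }
  m <- .charMatrix(seqs)
  if (ncol(m) != length(pat)) {
    stop("sequence/pattern length mismatch", call. = FALSE)
  }
  ok <- rep(TRUE, length(seqs))
  for (j in seq_along(pat)) {
    allowed <- strsplit(cls[j], "")[[1]]
    ok <- ok & (m[, j] %in% allowed)
  }
  ok
}

.matchesAnyPam <- function(seqs, pamPatterns) {
  hit <- rep(FALSE, length(seqs))
  for (p in pamPatterns) hit <- hit | .matchesIupac(seqs, p)
  hit
}

## character matrix (one row per sequence) for equal-length strings
.charMatrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(character(), nrow = 0L))
  matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.complementBase <- function(x) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N")[x]
}

## Parse "chrom:start-end" (1-based inclusive); NA fields if not a region string
.parseRegionString <- function(x) {
  m <- regmatches(x, regexec("^([^:[:space:]]+):([0-9]+)-([0-9]+)$", x))[[1]]
  if (length(m) == 0L) return(NULL)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

## Run expr with a fixed seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## 0-based half-open string id for a guide
.guideId <- function(chrom, start1, end1, strand) {
  sprintf("%s:%d-%d:%s", chrom, start1 - 1L, end1, strand)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
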