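## Shared fixtures and independent oracles. Oracle implementations here are
## deliberately naive (regex scans, double sums, full retranslation) and
## share no code with the package internals they check.

.fixtureEnv <- new.env(parent = emptyenv())

## One fixture per session, loaded lazily and cached.
fixtureData <- function(seed = 101L) {
  key <- paste0("fx", seed)
  if (is.null(.fixtureEnv[[key]])) {
    dir <- file.path(tempdir(), paste0("betiler_fx_", seed))
    fx <- generateFixture(dir, seed = seed)
    genome <- loadGenome(fx$fasta)
    ann <- loadAnnotation(fx$gff3, genome)
    .fixtureEnv[[key]] <- list(paths = fx, genome = genome, annotation = ann)
  }
  .fixtureEnv[[key]]
}

## Small hand-built genome: one chromosome from an explicit sequence.
toyGenome <- function(seq, chrom = "chr1") {
  GenomeAssembly(setNames(seq, chrom), "toy")
}

## Hand-built guide GRanges (1-based closed protospacer interval).
toyGuide <- function(genome, chrom, start, strand, length = 20L,
                     libraryType = "target", label = "toy") {
  end <- start + length - 1L
  proto <- beTiler:::.genomeSubseq(genome, chrom, start, end, strand)
  pam <- if (strand == "+") {
    beTiler:::.genomeSubseq(genome, chrom, end + 1L, end + 3L, "+")
  } else {
    beTiler:::.genomeSubseq(genome, chrom, start - 3L, start - 1L, "-")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$guide_id <- sprintf("%s:%d-%d:%s", chrom, start - 1L,
                                           end, strand)
  S4Vectors::mcols(gr)$protospacer <- proto
  S4Vectors::mcols(gr)$pam <- pam
  S4Vectors::mcols(gr)$source_label <- label
  S4Vectors::mcols(gr)$library_type <- libraryType
  gr
}

revcompStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## ---- off-target oracle: naive regex full-genome rescan --------------------

iupacToRegex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(pattern, "")[[1]]], collapse = "")
}

## All (chrom, strand, start, end, site, pam) windows with an allowed PAM
## and Hamming distance <= maxMismatches, via plain substring + regex.
oracleOfftargets <- function(protospacer, genome, pamPatterns, maxMismatches,
                             protoLen = 20L, pamLen = 3L) {
  regexes <- vapply(pamPatterns,
                    function(p) paste0("^", iupacToRegex(p), "$"), "")
  gchars <- strsplit(protospacer, "")[[1]]
  seqs <- genomeSequences(genome)
  hits <- list()
  for (ch in names(seqs)) {
    s <- as.character(seqs[[ch]])
    n <- nchar(s)
    for (strand in c("+", "-")) {
      str <- if (strand == "+") s else revcompStr(s)
      if (n < protoLen + pamLen) next
      starts <- seq_len(n - protoLen - pamLen + 1L)
      pams <- substring(str, starts + protoLen, starts + protoLen + pamLen - 1L)
      pamOk <- Reduce(`|`, lapply(regexes, function(r) grepl(r, pams)))
      starts <- starts[pamOk]
      pams <- pams[pamOk]
      sites <- substring(str, starts, starts + protoLen - 1L)
      keep <- !grepl("N", sites, fixed = TRUE)
      starts <- starts[keep]; pams <- pams[keep]; sites <- sites[keep]
      mm <- vapply(sites, function(x) {
        sum(strsplit(x, "")[[1]] != gchars)
      }, integer(1), USE.NAMES = FALSE)
      sel <- mm <= maxMismatches
      if (!any(sel)) next
      gs <- if (strand == "+") starts[sel]
            else n - (starts[sel] + protoLen - 1L) + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = ch, strand = strand, start = gs, end = gs + protoLen - 1L,
        site_sequence = sites[sel], pam = pams[sel], n_mismatches = mm[sel],
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      site_sequence = character(), pam = character(),
                      n_mismatches = integer()))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

## ---- Gini oracle: literal double sum --------------------------------------

oracleGini <- function(x) {
  n <- length(x)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) tot <- tot + abs(x[i] - x[j])
  tot / (2 * n * sum(x))
}

## ---- restriction-site oracle: substring scan both strands -----------------

oracleCountSites <- function(sequence, site) {
  cnt <- 0L
  for (s in c(site, revcompStr(site))) {
    L <- nchar(s)
    for (i in seq_len(max(0L, nchar(sequence) - L + 1L))) {
      if (substr(sequence, i, i + L - 1L) == s) cnt <- cnt + 1L
    }
  }
  cnt
}

## ---- consequence oracle: splice positions + full-CDS retranslation --------

## Severity-top outcome of one substitution set against one transcript,
## computed by mutating the chromosome sequence, rebuilding the spliced CDS
## and comparing the full translations.
oracleConsequence <- function(subs, tx, genome) {
  if (nrow(subs) == 0L || tx@chrom != subs$chrom[1]) return(NA_character_)
  exSt <- IRanges::start(tx@exons)
  exEn <- IRanges::end(tx@exons)
  near <- any(vapply(subs$pos, function(p) any(p >= exSt - 8 & p <= exEn + 8),
                     TRUE))
  if (!near || nrow(subs) == 0L) return(NA_character_)
  splicePos <- integer(0)
  if (length(tx@exons) > 1L) {
    for (k in seq_len(length(tx@exons) - 1L)) {
      splicePos <- c(splicePos, exEn[k] + 1L, exEn[k] + 2L,
                     exSt[k + 1L] - 2L, exSt[k + 1L] - 1L)
    }
  }
  if (any(subs$pos %in% splicePos)) return("splice")

  chromSeq <- strsplit(as.character(genomeSequences(genome)[[tx@chrom]]),
                       "")[[1]]
  mutSeq <- chromSeq
  mutSeq[subs$pos] <- subs$alt
  spliceCds <- function(chars) {
    pieces <- vapply(seq_along(tx@cds), function(i) {
      paste(chars[IRanges::start(tx@cds)[i]:IRanges::end(tx@cds)[i]],
            collapse = "")
    }, "")
    s <- paste(pieces, collapse = "")
    if (tx@strand == "-") s <- revcompStr(s)
    s
  }
  refCds <- spliceCds(chromSeq)
  mutCds <- spliceCds(mutSeq)
  if (nchar(refCds) == 0L || refCds == mutCds) return("noncoding")
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), no.init.codon = TRUE))
  refAA <- tr(refCds)
  mutAA <- tr(mutCds)
  refStop <- regexpr("[*]", refAA)
  mutStop <- regexpr("[*]", mutAA)
  if (substr(mutCds, 1, 3) != "ATG" && substr(refCds, 1, 3) == "ATG") {
    return("nonsense")                               # start codon lost
  }
  if (mutStop > 0 && (refStop < 0 || mutStop < refStop)) {
    return("nonsense")                               # stop gained
  }
  if (mutAA != refAA) return("missense")
  return("synonymous")
}
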