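## Build a PredictedEdit directly from a substitution table.
mkEdit <- function(chrom, pos, ref, alt) {
  subs <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                     alt = alt, stringsAsFactors = FALSE)
  methods::new("PredictedEdit", guideId = "toy", editorName = "toy",
               substitutions = subs, nEditedBases = nrow(subs),
               perTranscript = data.frame(),
               aggregatedOutcome = character(0))
}

## Genome with one + strand guide at position 11 whose protospacer is given.
guideGenome <- function(proto, pad5 = strrep("A", 10)) {
  toyGenome(paste0(pad5, proto, "TGG", strrep("A", 10)))
}

test_that("enumerateEdits mutates every editable window base simultaneously", {
  ## protospacer positions 4..8 = C,A,C,G,T; CBE window 4-8
  proto <- paste0("AAA", "CACGT", strrep("A", 12))
  g <- guideGenome(proto)
  guide <- toyGuide(g, "chr1", 11, "+")
  cbe <- baseEditor("CBE", 4, 8, "C", "T")
  edit <- enumerateEdits(guide, cbe, g)
  ## positions 4 and 6 of the protospacer = genomic 14 and 16
  expect_equal(edit@substitutions$pos, c(14L, 16L))
  expect_equal(edit@substitutions$ref, c("C", "C"))
  expect_equal(edit@substitutions$alt, c("T", "T"))
  expect_equal(edit@nEditedBases, 2L)
})

test_that("GC-motif exclusion skips Cs preceded by G on the protospacer strand", {
  ## positions 3..8 = A,C,G,C,A,T; window 4-8: C4 (prec A) edited,
  ## C6 (prec G) skipped
  proto <- paste0("AA", "ACGCAT", strrep("A", 12))
  g <- guideGenome(proto)
  guide <- toyGuide(g, "chr1", 11, "+")
  edit <- enumerateEdits(guide, baseEditor("CBE", 4, 8, "C", "T",
                                           excludeGC = TRUE), g)
  expect_equal(edit@substitutions$pos, 14L)   # protospacer position 4
  ## without the flag both Cs are edited
  edit2 <- enumerateEdits(guide, baseEditor("CBE", 4, 8, "C", "T"), g)
  expect_equal(edit2@substitutions$pos, c(14L, 16L))

  ## window position 1: the adjacent genomic base is consulted
  protoC1 <- paste0("C", strrep("A", 19))
  gG <- toyGenome(paste0(strrep("A", 9), "G", protoC1, "TGG", "AAAA"))
  guideG <- toyGuide(gG, "chr1", 11, "+")
  eG <- enumerateEdits(guideG, baseEditor("CBE", 1, 5, "C", "T",
                                          excludeGC = TRUE), gG)
  expect_equal(eG@aggregatedOutcome, "no_edit")
})

test_that("a window without the reference base yields no_edit", {
  g <- guideGenome(strrep("A", 20))
  guide <- toyGuide(g, "chr1", 11, "+")
  edit <- enumerateEdits(guide, baseEditor("CBE", 4, 8, "C", "T"), g)
  expect_equal(edit@nEditedBases, 0L)
  expect_equal(nrow(edit@substitutions), 0L)
  expect_equal(edit@aggregatedOutcome, "no_edit")
})

test_that("minus-strand edits are reported complemented on the reference strand", {
  proto <- paste0("AAA", "CACGT", strrep("A", 12))
  plusSeq <- paste0(strrep("A", 10), proto, "TGG", strrep("A", 10))
  minusGenome <- toyGenome(revcompStr(plusSeq))
  n <- nchar(plusSeq)
  ## the + strand guide at [11,30] mirrors to a - strand guide at [n-29, n-10]
  guide <- toyGuide(minusGenome, "chr1", n - 30L + 1L, "-")
  expect_equal(S4Vectors::mcols(guide)$protospacer, proto)
  edit <- enumerateEdits(guide, baseEditor("CBE", 4, 8, "C", "T"),
                         minusGenome)
  ## protospacer positions 4 and 6 -> genomic end - pos + 1, alleles G>A
  gend <- n - 10L
  expect_setequal(edit@substitutions$pos, c(gend - 3L, gend - 5L))
  expect_equal(unique(edit@substitutions$ref), "G")
  expect_equal(unique(edit@substitutions$alt), "A")
})

test_that("consequence classification recognises the canonical micro-cases", {
  ## single-exon CDS ATG CAA TAA at [21,29]
  g <- toyGenome(paste0(strrep("A", 20), "ATGCAATAA", strrep("A", 20)))
  tx <- TranscriptModel("T1", "G1", "chr1", "+",
                        IRanges::IRanges(21, 29), IRanges::IRanges(21, 29),
                        isCanonical = TRUE)
  ## CAA -> TAA: stop gained
  pt <- annotateConsequence(mkEdit("chr1", 24, "C", "T"), list(T1 = tx), g)
  expect_equal(pt$consequences, "nonsense")
  ## CAA -> CGA: Gln -> Arg missense
  pt <- annotateConsequence(mkEdit("chr1", 25, "A", "G"), list(T1 = tx), g)
  expect_equal(pt$consequences, "missense")
  ## start codon lost
  pt <- annotateConsequence(mkEdit("chr1", 21, "A", "G"), list(T1 = tx), g)
  expect_equal(pt$consequences, "nonsense")

  ## CTG -> CTA: Leu -> Leu synonymous (CDS ATG CTG TAA)
  g2 <- toyGenome(paste0(strrep("A", 20), "ATGCTGTAA", strrep("A", 20)))
  tx2 <- TranscriptModel("T1", "G1", "chr1", "+",
                         IRanges::IRanges(21, 29), IRanges::IRanges(21, 29))
  pt <- annotateConsequence(mkEdit("chr1", 26, "G", "A"), list(T1 = tx2), g2)
  expect_equal(pt$consequences, "synonymous")

  ## corruption guard: ref allele must match the genome
  expect_error(annotateConsequence(mkEdit("chr1", 24, "G", "T"),
                                   list(T1 = tx2), g2), "mismatch")
})

test_that("splice sites, UTRs and intergenic edits classify correctly", {
  ## two exons [21,29] and [60,71], intron [30,59]
  seq <- paste0(strrep("A", 20), "ATGCAACAA", strrep("T", 30),
                "CAACAACAATAA", strrep("A", 20))
  g <- toyGenome(seq)
  tx <- TranscriptModel("T1", "G1", "chr1", "+",
                        IRanges::IRanges(c(21, 60), c(29, 71)),
                        IRanges::IRanges(c(21, 60), c(29, 71)))
  txs <- list(T1 = tx)
  ## intron position +1 after the donor exon boundary -> splice
  pt <- annotateConsequence(mkEdit("chr1", 30, "T", "C"), txs, g)
  expect_equal(pt$consequences, "splice")
  ## acceptor -1 position -> splice
  pt <- annotateConsequence(mkEdit("chr1", 59, "T", "C"), txs, g)
  expect_equal(pt$consequences, "splice")
  ## deep intron (but within 8 nt of an exon) -> noncoding
  pt <- annotateConsequence(mkEdit("chr1", 33, "T", "C"), txs, g)
  expect_equal(pt$consequences, "noncoding")
  ## far from any exon -> no row (aggregates to noncoding)
  pt <- annotateConsequence(mkEdit("chr1", 45, "T", "C"), txs, g)
  expect_equal(nrow(pt), 0L)
  agg <- aggregateOutcome(pt, txs)
  expect_equal(agg$outcome, "noncoding")

  ## UTR exon base -> noncoding
  tx3 <- TranscriptModel("T2", "G1", "chr1", "+",
                         IRanges::IRanges(21, 40), IRanges::IRanges(21, 29))
  pt <- annotateConsequence(mkEdit("chr1", 33, "T", "C"), list(T2 = tx3), g)
  expect_equal(pt$consequences, "noncoding")
})

test_that("aggregation follows severity within the picked isoform", {
  txA <- TranscriptModel("A", "G1", "chr1", "+", IRanges::IRanges(1, 30),
                         IRanges::IRanges(1, 30), isCanonical = TRUE)
  txB <- TranscriptModel("B", "G1", "chr1", "+", IRanges::IRanges(1, 60),
                         IRanges::IRanges(1, 60))
  txs <- list(A = txA, B = txB)
  pt <- data.frame(transcript_id = c("A", "B"), gene_name = "G1",
                   consequences = c("missense", "synonymous"),
                   is_canonical = c(TRUE, FALSE), stringsAsFactors = FALSE)
  agg <- aggregateOutcome(pt, txs)
  expect_equal(agg$outcome, "missense")
  expect_equal(agg$pick_transcript, "A")
  expect_true(agg$pick_is_canonical)

  ## multiple classes on the picked isoform: splice wins
  pt2 <- data.frame(transcript_id = "A", gene_name = "G1",
                    consequences = "splice,nonsense", is_canonical = TRUE,
                    stringsAsFactors = FALSE)
  expect_equal(aggregateOutcome(pt2, txs)$outcome, "splice")

  ## no canonical overlap: longest CDS wins
  pt3 <- data.frame(transcript_id = c("B"), gene_name = "G1",
                    consequences = "synonymous", is_canonical = FALSE,
                    stringsAsFactors = FALSE)
  expect_equal(aggregateOutcome(pt3, txs)$pick_transcript, "B")

  ## empty overlap set -> noncoding
  expect_equal(aggregateOutcome(pt3[0, ], txs)$outcome, "noncoding")
})

test_that("guides inserting the same variant share a variant key", {
  ## one C at position 31; two overlapping + strand guides cover it in
  ## their 4-8 windows
  seq <- strsplit(strrep("A", 60), "")[[1]]
  seq[31] <- "C"
  seq[48] <- "G"; seq[49] <- "G"; seq[50] <- "G"
  g <- toyGenome(paste(seq, collapse = ""))
  gA <- toyGuide(g, "chr1", 28, "+")   # C at protospacer position 4
  gB <- toyGuide(g, "chr1", 27, "+")   # C at protospacer position 5
  guides <- c(gA, gB)
  tab <- annotateLibrary(guides, list(baseEditor("CBE", 4, 8, "C", "T")),
                         g, list())
  blk <- libraryAnnotations(tab)$CBE
  expect_equal(blk$n_edited_bases, c(1L, 1L))
  expect_equal(blk$variant_key[1], blk$variant_key[2])
  expect_equal(blk$substitutions[1], "chr1:g.31C>T")
})

test_that("annotation blocks are per-editor and disagree where computed", {
  ## protospacer window 4-8 = CCAAA: Cs but no As... use C at 4,5 only
  proto <- paste0("AAA", "CC", strrep("T", 15))
  g <- guideGenome(proto)
  guide <- toyGuide(g, "chr1", 11, "+")
  tab <- annotateLibrary(guide,
                         list(baseEditorPreset("BE4"),
                              baseEditorPreset("ABE8e")),
                         g, list())
  ann <- libraryAnnotations(tab)
  expect_named(ann, c("BE4", "ABE8e"))
  expect_equal(nrow(ann$BE4), 1L)
  expect_equal(ann$BE4$guide_id, ann$ABE8e$guide_id)
  expect_equal(ann$BE4$aggregated_outcome, "noncoding")  # edits, no transcript
  expect_equal(ann$ABE8e$aggregated_outcome, "no_edit")  # no A in window
})

test_that("edits always fall inside the window projection (fixture sweep)", {
  fx <- fixtureData()
  region <- GenomicRanges::GRanges("chrE", IRanges::IRanges(
    1, chromLengths(fx$genome)[["chrE"]]))
  S4Vectors::mcols(region)$label <- "ESS1"
  guides <- scanGuides(region, fx$genome, casVariantPreset("SpCas9"))
  ed <- baseEditorPreset("BE4")
  edGC <- baseEditor("BE4gc", 4, 8, "C", "T", excludeGC = TRUE)
  for (i in seq_along(guides)) {
    st <- GenomicRanges::start(guides)[i]
    en <- GenomicRanges::end(guides)[i]
    sd <- as.character(GenomicRanges::strand(guides))[i]
    proto <- S4Vectors::mcols(guides)$protospacer[i]
    edit <- enumerateEdits(guides[i], ed, fx$genome)
    if (nrow(edit@substitutions)) {
      lo <- if (sd == "+") st + 3L else en - 7L
      hi <- if (sd == "+") st + 7L else en - 3L
      expect_true(all(edit@substitutions$pos >= lo &
                      edit@substitutions$pos <= hi))
    }
    ## GC exclusion never edits a GC-motif C, and edited set is a subset
    editGC <- enumerateEdits(guides[i], edGC, fx$genome)
    expect_true(all(editGC@substitutions$pos %in% edit@substitutions$pos))
    if (nrow(editGC@substitutions)) {
      protoPos <- if (sd == "+") editGC@substitutions$pos - st + 1L
                  else en - editGC@substitutions$pos + 1L
      prev <- substring(proto, protoPos - 1L, protoPos - 1L)
      expect_false(any(prev == "G"))
    }
  }
})

test_that("codon-level classification matches full-CDS retranslation (oracle)", {
  fx <- fixtureData()
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    1, chromLengths(fx$genome)[["chr1"]]))
  S4Vectors::mcols(region)$label <- "all"
  guides <- scanGuides(region, fx$genome, casVariantPreset("SpCas9"))
  editors <- list(baseEditorPreset("BE4"), baseEditorPreset("ABE8e"))
  nChecked <- 0L
  for (ed in editors) {
    for (i in seq_along(guides)) {
      edit <- enumerateEdits(guides[i], ed, fx$genome)
      if (nrow(edit@substitutions) == 0L) next
      pt <- annotateConsequence(edit, fx$annotation, fx$genome)
      for (tx in fx$annotation) {
        want <- oracleConsequence(edit@substitutions, tx, fx$genome)
        got <- if (tx@transcriptId %in% pt$transcript_id) {
          strsplit(pt$consequences[pt$transcript_id == tx@transcriptId],
                   ",")[[1]][1]
        } else NA_character_
        expect_identical(got, want)
        if (!is.na(want)) nChecked <- nChecked + 1L
      }
    }
  }
  expect_gte(nChecked, 50L)
})
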