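mkGuideDf <- function(protospacers, type = "target", prefix = "g") {
  data.frame(guide_id = paste0(prefix, seq_along(protospacers)),
             protospacer = protospacers, library_type = type,
             stringsAsFactors = FALSE)
}

randomSpacers <- function(n, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  }, "")
}

test_that("enzyme site counting matches the substring-scan oracle", {
  set.seed(5)
  for (rep in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
               collapse = "")
    ## spike sites into some sequences
    if (rep %% 3 == 0) s <- paste0(s, "CGTCTC", s)
    if (rep %% 4 == 0) s <- paste0("GAATTC", s, "GAGACG")
    for (e in c("BsmBI", "EcoRI")) {
      site <- c(BsmBI = "CGTCTC", EcoRI = "GAATTC")[[e]]
      expect_identical(as.integer(countEnzymeSites(s, e)),
                       oracleCountSites(s, site))
    }
  }
})

test_that("the default template carries exactly the designed BsmBI sites", {
  for (k in c(1L, 3L, 5L)) {
    tpl <- defaultOligomerTemplate(k)
    expect_identical(unname(tpl@designedSiteCounts["BsmBI"]), 2 * k)
  }
  tplS <- defaultSensorTemplate()
  expect_identical(unname(tplS@designedSiteCounts["BsmBI"]), 1)
  expect_identical(unname(tplS@designedSiteCounts["EcoRI"]), 2)
})

test_that("deduplication keeps the highest-precedence copy", {
  df <- rbind(mkGuideDf("ACGTACGTACGTACGTACGT", "negative", "n"),
              mkGuideDf("ACGTACGTACGTACGTACGT", "target", "t"),
              mkGuideDf("TTTTACGTACGTACGTACGT", "positive", "p"))
  dd <- deduplicateGuides(df)
  expect_equal(nrow(dd$unique), 2L)
  kept <- dd$unique[dd$unique$protospacer == "ACGTACGTACGTACGTACGT", ]
  expect_equal(kept$library_type, "target")
  expect_equal(dd$dropped$guide_id, "n1")
  expect_equal(dd$dropped$kept_twin, "t1")

  ## all-unique input: nothing dropped
  dd2 <- deduplicateGuides(mkGuideDf(randomSpacers(5, 1)))
  expect_equal(nrow(dd2$dropped), 0L)

  ## triple duplicate: exactly one kept
  df3 <- mkGuideDf(rep("ACGTACGTACGTACGTACGT", 3))
  dd3 <- deduplicateGuides(df3)
  expect_equal(nrow(dd3$unique), 1L)
  expect_equal(dd3$unique$guide_id, "g1")  # first in input order
})

test_that("restriction filtering removes internal and junction-formed sites", {
  tpl <- defaultOligomerTemplate(3)
  df <- mkGuideDf(c(
    "AAAAAAACGTCTCAAAAAAA",   # internal BsmBI site
    "AAAAAAAAAAAAAAAGAGAC",   # suffix + following linker G -> GAGACG
    "TCTCAAAAAAAAAAAAAAAA",   # preceding linker ...ACCG + TCTC -> CGTCTC
    "ACGTACGTACGTACGTACGT"))  # clean
  res <- filterRestrictionSites(df, tpl)
  expect_setequal(res$removed$guide_id, c("g1", "g2", "g3"))
  expect_equal(res$kept$guide_id, "g4")
  expect_match(res$reasons$reason[1], "BsmBI")

  ## independent check: the clean spacer really adds no site in any slot
  for (slot in 1:3) {
    spacers <- rep(beTiler:::.DUMMY_SPACER, 3)
    spacers[slot] <- "ACGTACGTACGTACGTACGT"
    oligo <- beTiler:::.buildOligomer(tpl, spacers)
    expect_identical(oracleCountSites(oligo, "CGTCTC"), 6L)
  }
})

test_that("padding fills from negatives, then positives, then trims targets", {
  targets <- mkGuideDf(randomSpacers(10, 2), "target", "t")
  negPool <- mkGuideDf(randomSpacers(3, 3), "negative", "n")
  posPool <- mkGuideDf(randomSpacers(3, 4), "positive", "p")

  ## 14 selected, k=3 -> 1 negative added
  sel <- rbind(targets, mkGuideDf(randomSpacers(4, 5), "negative", "sn"))
  pad <- padToMultiple(sel, negPool, posPool, k = 3, seed = 9)
  expect_equal(nrow(pad$final) %% 3, 0L)
  expect_equal(nrow(pad$final), 15L)
  expect_equal(pad$report$action, "added")
  expect_equal(pad$report$library_type, "negative")

  ## empty pools, 10 targets, k=3 -> 1 target removed
  pad2 <- padToMultiple(targets, NULL, NULL, k = 3, seed = 9)
  expect_equal(nrow(pad2$final), 9L)
  expect_equal(pad2$report$action, "removed")
  expect_true(all(pad2$report$guide_id %in% targets$guide_id))

  ## cascade: deficit 2, one negative available, positives fill the rest
  pad3 <- padToMultiple(targets, negPool[1, ], posPool, k = 4, seed = 9)
  expect_equal(nrow(pad3$final), 12L)
  expect_setequal(pad3$report$library_type, c("negative", "positive"))

  ## already a multiple: unchanged, empty report
  pad4 <- padToMultiple(targets[1:9, ], negPool, posPool, k = 3, seed = 9)
  expect_equal(nrow(pad4$final), 9L)
  expect_equal(nrow(pad4$report), 0L)

  ## determinism
  pad5 <- padToMultiple(sel, negPool, posPool, k = 3, seed = 9)
  expect_identical(pad$final, pad5$final)
})

test_that("oligomer assembly partitions guides into k-sized groups", {
  tpl <- defaultOligomerTemplate(3)
  df <- mkGuideDf(randomSpacers(15, 6))
  asm <- assembleOligomers(df, tpl, seed = 4)
  expect_equal(nrow(asm$oligos), 5L)
  expect_setequal(asm$slots$guide_id, df$guide_id)
  expect_equal(anyDuplicated(asm$slots$guide_id), 0L)
  expect_equal(unname(table(asm$slots$oligo_id)), rep(3L, 5L),
               ignore_attr = TRUE)
  ## fixed-length oligomers
  expect_length(unique(nchar(asm$oligos$sequence)), 1L)
  ## sequence equals the template instantiated with the slot spacers
  o1 <- asm$slots[asm$slots$oligo_id == asm$oligos$oligo_id[1], ]
  expect_identical(asm$oligos$sequence[1],
                   beTiler:::.buildOligomer(tpl, o1$protospacer))

  ## k = 1: one oligomer per guide
  asm1 <- assembleOligomers(df, defaultOligomerTemplate(1), seed = 4)
  expect_equal(nrow(asm1$oligos), 15L)

  ## determinism
  asm2 <- assembleOligomers(df, tpl, seed = 4)
  expect_identical(asm$oligos, asm2$oligos)

  ## precondition: multiples of k only
  expect_error(assembleOligomers(df[1:14, ], tpl, seed = 4), "multiple")
})

test_that("control selection is seeded, filtered and non-overlapping", {
  negCore <- mkGuideDf(randomSpacers(10, 7), "negative", "n")
  negTab <- LibraryTable(negCore, list(), "negative")
  s1 <- selectControls(negTab, NULL, nNegative = 4, seed = 3)
  s2 <- selectControls(negTab, NULL, nNegative = 4, seed = 3)
  expect_identical(s1$negatives, s2$negatives)
  expect_equal(nrow(s1$negatives), 4L)
  expect_error(selectControls(negTab, NULL, nNegative = 11, seed = 3),
               "only 10 available")

  posCore <- mkGuideDf(randomSpacers(6, 8), "positive", "p")
  blk <- data.frame(guide_id = posCore$guide_id, editor = "BE4",
                    aggregated_outcome = c("nonsense", "nonsense", "missense",
                                           "missense", "splice", "no_edit"),
                    stringsAsFactors = FALSE)
  posTab <- LibraryTable(posCore, list(BE4 = blk), "positive")
  sel <- selectControls(NULL, posTab, 0,
                        list(list(editor = "BE4", outcome = "nonsense", n = 1),
                             list(editor = "BE4", outcome = "nonsense", n = 1)),
                        seed = 5)
  expect_equal(nrow(sel$positives), 2L)
  expect_equal(anyDuplicated(sel$positives$guide_id), 0L)
  ## shortfall names the outcome and the available count
  expect_error(
    selectControls(NULL, posTab, 0,
                   list(list(editor = "BE4", outcome = "splice", n = 2)),
                   seed = 5),
    "BE4/splice: requested 2, available 1")
})

test_that("sensor oligos embed the exact genomic window and filter sites", {
  set.seed(12)
  backbone <- paste(sample(c("A", "C", "T"), 120, replace = TRUE),
                    collapse = "")
  g <- toyGenome(paste0(backbone, strrep("A", 20), "TGGAAAAAAAAAAA",
                        strrep("C", 10)))
  start <- nchar(backbone) + 1L
  guide <- toyGuide(g, "chr1", start, "+")
  tpl <- defaultSensorTemplate()
  res <- assembleSensorOligos(guidesToDataFrame(guide), tpl, g)
  expect_equal(nrow(res$oligos), 1L)
  ## sensor = 7 nt up + protospacer + PAM + 10 nt down, re-extractable
  sensor <- res$oligos$sensor
  expect_equal(nchar(sensor), 40L)
  expect_identical(sensor, beTiler:::.genomeSubseq(g, "chr1", start - 7L,
                                                   start + 32L, "+"))
  expect_true(grepl(sensor, res$oligos$sequence, fixed = TRUE))
  expect_equal(nchar(res$oligos$sequence), 209L)

  ## guide too close to the chromosome start is dropped with a warning
  gEdge <- toyGenome(paste0("AA", strrep("A", 20), "TGG", strrep("A", 30)))
  guideEdge <- toyGuide(gEdge, "chr1", 3, "+")
  expect_warning(
    resEdge <- assembleSensorOligos(guidesToDataFrame(guideEdge), tpl, gEdge),
    "outside chromosome")
  expect_equal(nrow(resEdge$oligos), 0L)

  ## EcoRI site inside the sensor window eliminates the oligo
  gEco <- toyGenome(paste0(backbone, strrep("A", 20), "TGG", "GAATTC",
                           strrep("A", 20)))
  guideEco <- toyGuide(gEco, "chr1", start, "+")
  resEco <- assembleSensorOligos(guidesToDataFrame(guideEco), tpl, gEco)
  expect_equal(nrow(resEco$oligos), 0L)
  expect_match(resEco$removed$reason, "EcoRI")
})

test_that("order file and manifest reflect the assembled library", {
  tpl <- defaultOligomerTemplate(3)
  df <- mkGuideDf(randomSpacers(9, 13))
  asm <- assembleOligomers(df, tpl, seed = 2)
  p <- tempfile()
  writeOrderFile(asm$oligos, p)
  expect_equal(readLines(p), asm$oligos$sequence)
  mp <- tempfile(fileext = ".csv")
  manifest <- writePreparedLibrary(df, asm$slots, mp)
  expect_equal(nrow(manifest), 9L)
  expect_true(all(c("oligo_id", "slot") %in% colnames(manifest)))
  back <- read.csv(mp, stringsAsFactors = FALSE)
  expect_equal(back$guide_id, manifest$guide_id)
})
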