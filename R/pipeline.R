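## End-to-end wrappers tying the stages together: design -> annotate
## (designLibrary) and merge -> dedup -> filter -> pad -> assemble -> write
## (assembleLibrary). These are what the command-line front-end and most
## interactive sessions call.

#' Design and annotate an sgRNA library
#'
#' Resolves target entries, scans guides, applies off-target filtering
#' (SpCas9-family variants only), attaches on-target scores and per-editor
#' outcome annotations, and returns a [LibraryTable-class].
#'
#' @param genome A [GenomeAssembly-class].
#' @param annotation Named list of [TranscriptModel-class].
#' @param entries Gene names and/or `"chrom:start-end"` region strings.
#' @param cas A [CasVariant-class].
#' @param editors List of [BaseEditor-class] objects.
#' @param flankNt Flank added to each resolved interval.
#' @param canonicalOnly Restrict gene entries to canonical isoforms.
#' @param blacklist Optional blacklist `GRanges`.
#' @param libraryType `"target"`, `"positive"` or `"negative"`.
#' @param maxOfftargets,cfdThreshold,maxMismatches Off-target thresholds
#'   (defaults 0 / 0.2 / 3).
#' @param offtargetFilter Set `FALSE` to skip off-target filtering.
#' @param scorer On-target scorer passed to [onTargetScore()].
#' @param maxTotalSpanNt Total-span cap for [resolveTargets()].
#' @return A [LibraryTable-class].
#' @export
designLibrary <- function(genome, annotation, entries, cas, editors,
                          flankNt = 0L, canonicalOnly = FALSE,
                          blacklist = NULL, libraryType = "target",
                          maxOfftargets = 0L, cfdThreshold = 0.2,
                          maxMismatches = 3L, offtargetFilter = TRUE,
                          scorer = "surrogate",
                          maxTotalSpanNt = 1500000L) {
  regions <- resolveTargets(entries, annotation, genome, flankNt = flankNt,
                            canonicalOnly = canonicalOnly,
                            blacklist = blacklist,
                            maxTotalSpanNt = maxTotalSpanNt)
  guides <- scanGuideSet(regions, genome, cas, libraryType = libraryType)
  if (offtargetFilter && cas@isSpCas9Family) {
    flt <- filterByOfftargets(guides, genome, cas,
                              maxOfftargets = maxOfftargets,
                              cfdThreshold = cfdThreshold,
                              maxMismatches = maxMismatches)
    guides <- flt$kept
  }
  guides <- onTargetScore(guides, genome, scorer = scorer)
  annotateLibrary(guides, editors, genome, annotation,
                  libraryType = libraryType)
}

#' Assemble an sgRNA library into order-ready oligonucleotides
#'
#' Merges the target library with seeded random selections of negative and
#' positive controls, deduplicates on protospacer (precedence target >
#' positive > negative), filters restriction-site creation/reconstitution,
#' pads the count to a multiple of k (add negatives, then positives, then
#' remove targets), assembles oligomers (or per-guide sensor oligos) and
#' optionally writes the order file and `Prepared_library.csv`. A
#' conservation audit reconciling every count is returned.
#'
#' @param targetTable Target [LibraryTable-class].
#' @param negativeTable,positiveTable Optional control [LibraryTable-class]s.
#' @param nNegative Number of negative controls to include.
#' @param positiveRequests List of `list(editor=, outcome=, n=)`.
#' @param mode `"standard"` (multiplexed golden-gate) or `"sensor"`.
#' @param template [OligomerTemplate-class] for standard mode.
#' @param sensorTemplate [SensorTemplate-class] for sensor mode.
#' @param genome [GenomeAssembly-class]; required in sensor mode.
#' @param seed Single seed governing selection, padding and shuffling.
#' @param outDir If non-`NULL`, write `oligo_order.txt`,
#'   `Prepared_library.csv` and `change_report.csv` there.
#' @return List: `final` (manifest data.frame), `oligos`, `slots` (standard
#'   mode), `changeReport`, `audit` (named counts reconciling input to
#'   manifest), and `files` when `outDir` is given.
#' @export
assembleLibrary <- function(targetTable, negativeTable = NULL,
                            positiveTable = NULL, nNegative = 0L,
                            positiveRequests = list(),
                            mode = c("standard", "sensor"),
                            template = defaultOligomerTemplate(3L),
                            sensorTemplate = defaultSensorTemplate(),
                            genome = NULL, seed = 1L, outDir = NULL) {
  mode <- match.arg(mode)
  ctrl <- selectControls(negativeTable, positiveTable, nNegative,
                         positiveRequests, seed = seed)
  coreCols <- colnames(targetTable@core)
  pool <- function(tab, sel) {
    if (is.null(tab)) return(NULL)
    unused <- tab@core[!(tab@core$guide_id %in% sel$guide_id), , drop = FALSE]
    unused[, coreCols, drop = FALSE]
  }
  selNeg <- if (is.null(ctrl$negatives)) targetTable@core[0, ] else
    ctrl$negatives[, coreCols, drop = FALSE]
  selPos <- if (is.null(ctrl$positives)) targetTable@core[0, ] else
    ctrl$positives[, coreCols, drop = FALSE]
  combined <- rbind(targetTable@core, selPos, selNeg)
  rownames(combined) <- NULL
  nInput <- nrow(combined)

  dd <- deduplicateGuides(combined)
  if (mode == "standard") {
    rf <- filterRestrictionSites(dd$unique, template)
    negPool <- pool(negativeTable, selNeg)
    posPool <- pool(positiveTable, selPos)
    ## pool guides must survive the same restriction filter before padding
    if (!is.null(negPool) && nrow(negPool)) {
      negPool <- filterRestrictionSites(negPool, template)$kept
    }
    if (!is.null(posPool) && nrow(posPool)) {
      posPool <- filterRestrictionSites(posPool, template)$kept
    }
    pad <- padToMultiple(rf$kept, negPool, posPool, template@k,
                         seed = seed + 1L)
    asm <- assembleOligomers(pad$final, template, seed = seed + 2L)
    final <- pad$final
    slots <- asm$slots
    oligos <- asm$oligos
    sensorRemoved <- 0L
    padAdded <- sum(pad$report$action == "added")
    padRemoved <- sum(pad$report$action == "removed")
    changeReport <- pad$report
  } else {
    if (is.null(genome)) .stopf("sensor mode requires the genome")
    rfRemoved <- 0L
    asm <- assembleSensorOligos(dd$unique, sensorTemplate, genome)
    keep <- dd$unique$guide_id %in% asm$oligos$guide_id
    final <- dd$unique[keep, , drop = FALSE]
    slots <- data.frame(oligo_id = asm$oligos$oligo_id, slot = 1L,
                        guide_id = asm$oligos$guide_id,
                        protospacer = final$protospacer[
                          match(asm$oligos$guide_id, final$guide_id)],
                        stringsAsFactors = FALSE)
    oligos <- asm$oligos
    sensorRemoved <- nrow(asm$removed)
    padAdded <- 0L
    padRemoved <- 0L
    rf <- list(removed = dd$unique[0, ])
    changeReport <- data.frame(action = character(), guide_id = character(),
                               library_type = character())
  }

  audit <- c(input = nInput,
             dedup_dropped = nrow(dd$dropped),
             restriction_dropped = nrow(rf$removed),
             sensor_dropped = sensorRemoved,
             padding_added = padAdded,
             padding_removed = padRemoved,
             manifest_rows = nrow(final))

  files <- NULL
  manifest <- final
  if (!is.null(slots)) {
    idx <- match(manifest$guide_id, slots$guide_id)
    manifest$oligo_id <- slots$oligo_id[idx]
    manifest$slot <- slots$slot[idx]
  }
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    orderPath <- file.path(outDir, "oligo_order.txt")
    manifestPath <- file.path(outDir, "Prepared_library.csv")
    reportPath <- file.path(outDir, "change_report.csv")
    writeOrderFile(oligos, orderPath)
    write.csv(manifest, manifestPath, row.names = FALSE)
    write.csv(changeReport, reportPath, row.names = FALSE)
    files <- c(order = orderPath, manifest = manifestPath,
               change_report = reportPath)
  }
  list(final = manifest, oligos = oligos, slots = slots,
       changeReport = changeReport, dedupDropped = dd$dropped,
       restrictionRemoved = rf$removed, audit = audit, files = files)
}
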