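## Library assembly: control selection, deduplication, restriction-site
## filtering, padding to multiples of k, oligomer / sensor-oligo construction
## and the order-file + manifest writers.

.ENZYME_SITES <- c(BsmBI = "CGTCTC", EcoRI = "GAATTC")

## 20-nt constant spacer free of BsmBI/EcoRI sites, used to probe templates
.DUMMY_SPACER <- "ACTGACTGACTGACTGACTG"
.DUMMY_SENSOR <- strrep("ACTG", 10L)

#' Count restriction recognition sites on both strands
#'
#' Occurrences of the recognition sequence on the forward strand plus
#' occurrences of its reverse complement (overlapping matches counted).
#'
#' @param sequence DNA string.
#' @param enzyme `"BsmBI"` or `"EcoRI"`, or a raw recognition sequence.
#' @return Integer site count.
#' @export
countEnzymeSites <- function(sequence, enzyme) {
  site <- if (enzyme %in% names(.ENZYME_SITES)) .ENZYME_SITES[[enzyme]]
          else enzyme
  s <- Biostrings::DNAString(sequence)
  Biostrings::countPattern(site, s) +
    Biostrings::countPattern(.revcomp(site), s)
}

## ---------------------------------------------------------------------------
## Templates
## ---------------------------------------------------------------------------

#' Multiplexed golden-gate oligomer template
#'
#' Layout: `left_primer + sum_i(linker_i + spacer_i) + terminal +
#' right_primer`. Each linker/terminal carries the designed BsmBI landing
#' sites; `designedSiteCounts` is the recognition-site count (both strands)
#' of the template assembled with site-free dummy spacers -- the baseline
#' against which reconstituted sites are detected. The shipped default
#' sequences are placeholders satisfying the structural invariants (correct
#' BsmBI placement, site-free elsewhere), not a published cloning protocol.
#'
#' @slot leftPrimer,rightPrimer Amplification primers.
#' @slot linkers One segment placed 5' of each sgRNA slot (length `k`).
#' @slot terminal Segment closing the last slot.
#' @slot k sgRNAs per oligomer.
#' @slot enzymes Enzyme set checked during filtering.
#' @slot primerPairLabel Label of the primer pair.
#' @slot designedSiteCounts Named baseline site counts.
#' @export
setClass("OligomerTemplate",
  representation(leftPrimer = "character", rightPrimer = "character",
                 linkers = "character", terminal = "character",
                 k = "integer", enzymes = "character",
                 primerPairLabel = "character",
                 designedSiteCounts = "numeric"))

setValidity("OligomerTemplate", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (length(object@linkers) != object@k) {
    return("need exactly one linker per sgRNA slot")
  }
  if (!all(object@enzymes %in% names(.ENZYME_SITES))) {
    return("unknown enzyme in enzyme set")
  }
  TRUE
})

.buildOligomer <- function(template, spacers) {
  paste0(template@leftPrimer,
         paste0(template@linkers, spacers, collapse = ""),
         template@terminal, template@rightPrimer)
}

#' Construct an oligomer template
#'
#' @param leftPrimer,rightPrimer,linkers,terminal Template segments.
#' @param k sgRNAs per oligomer.
#' @param enzymes Enzymes to filter on (default BsmBI).
#' @param primerPairLabel Primer pair label.
#' @export
oligomerTemplate <- function(leftPrimer, rightPrimer, linkers, terminal,
                             k = length(linkers), enzymes = "BsmBI",
                             primerPairLabel = "custom") {
  obj <- new("OligomerTemplate", leftPrimer = toupper(leftPrimer),
             rightPrimer = toupper(rightPrimer), linkers = toupper(linkers),
             terminal = toupper(terminal), k = as.integer(k),
             enzymes = enzymes, primerPairLabel = primerPairLabel,
             designedSiteCounts = numeric(0))
  dummy <- .buildOligomer(obj, rep(.DUMMY_SPACER, obj@k))
  obj@designedSiteCounts <- vapply(enzymes, function(e) {
    as.numeric(countEnzymeSites(dummy, e))
  }, numeric(1))
  obj
}

#' Default golden-gate oligomer template
#'
#' Placeholder template with one BsmBI site opening and one closing each
#' sgRNA slot (2k designed sites in total) and two validated-format primer
#' pairs for pool multiplexing.
#'
#' @param k sgRNAs per oligomer (default 3, the multiplexing used for
#'   pooled synthesis).
#' @param primerPair `"pairA"` or `"pairB"`.
#' @return An [OligomerTemplate-class].
#' @export
defaultOligomerTemplate <- function(k = 3L, primerPair = c("pairA", "pairB")) {
  primerPair <- match.arg(primerPair)
  primers <- switch(primerPair,
    pairA = c("AGGCACTTGCATCGGTACAA", "TGTGGGATCACCTCTGGTCA"),
    pairB = c("CATGTTGCCCTAACGGTTCA", "ACACCGTTAGAGCCTGTGAT"))
  open <- "GCATTCGTCTCTACCG"        # forward BsmBI site opening a slot
  close <- "GTTTAGAGACGTG"          # reverse BsmBI site closing a slot
  linkers <- c(open, rep(paste0(close, open), max(0L, k - 1L)))[seq_len(k)]
  oligomerTemplate(primers[1], primers[2], linkers, close, k,
                   enzymes = "BsmBI", primerPairLabel = primerPair)
}

setMethod("show", "OligomerTemplate", function(object) {
  cat("OligomerTemplate (", object@primerPairLabel, "): k=", object@k,
      ", designed sites {",
      paste(sprintf("%s=%d", names(object@designedSiteCounts),
                    object@designedSiteCounts), collapse = ", "),
      "}\n", sep = "")
})

#' Sensor oligonucleotide template
#'
#' Layout: `left_primer + BsmBI arm + spacer + scaffold + sensor + EcoRI arm
#' + right_primer`, where the sensor is a 40-nt genomic window around the
#' guide's target site in protospacer-strand orientation (default split:
#' 7 nt upstream + 20 protospacer + 3 PAM + 10 nt downstream). The shipped
#' scaffold is the standard sgRNA scaffold; arm/primer sequences are
#' structural placeholders.
#'
#' @slot leftPrimer,rightPrimer,bsmbiArm,scaffold,ecoriArm Template segments.
#' @slot upstreamNt,downstreamNt Sensor window split around protospacer+PAM.
#' @slot designedSiteCounts Baseline BsmBI/EcoRI counts with dummy
#'   spacer and sensor.
#' @export
setClass("SensorTemplate",
  representation(leftPrimer = "character", rightPrimer = "character",
                 bsmbiArm = "character", scaffold = "character",
                 ecoriArm = "character", upstreamNt = "integer",
                 downstreamNt = "integer", designedSiteCounts = "numeric"))

.buildSensorOligo <- function(template, spacer, sensor) {
  paste0(template@leftPrimer, template@bsmbiArm, spacer, template@scaffold,
         sensor, template@ecoriArm, template@rightPrimer)
}

#' Default sensor template
#'
#' @param upstreamNt,downstreamNt Sensor window split (default 7/10, so the
#'   40-nt sensor centres the protospacer+PAM).
#' @return A [SensorTemplate-class].
#' @export
defaultSensorTemplate <- function(upstreamNt = 7L, downstreamNt = 10L) {
  scaffold <- paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTT",
                     "GAAAAAGTGGCACCGAGTCGGTGC")
  obj <- new("SensorTemplate",
             leftPrimer = "AGGCACTTGCATCGGTACAA",
             rightPrimer = "TGTGGGATCACCTCTGGTCA",
             bsmbiArm = "ATCTTCGTCTCTACCG",
             scaffold = scaffold,
             ecoriArm = "GTGAATTCCTAGACGGT",
             upstreamNt = as.integer(upstreamNt),
             downstreamNt = as.integer(downstreamNt),
             designedSiteCounts = numeric(0))
  dummy <- .buildSensorOligo(obj, .DUMMY_SPACER, .DUMMY_SENSOR)
  obj@designedSiteCounts <- vapply(c("BsmBI", "EcoRI"), function(e) {
    as.numeric(countEnzymeSites(dummy, e))
  }, numeric(1))
  obj
}

setMethod("show", "SensorTemplate", function(object) {
  cat("SensorTemplate: sensor = ", object@upstreamNt, "+20+3+",
      object@downstreamNt, " nt; designed sites {",
      paste(sprintf("%s=%d", names(object@designedSiteCounts),
                    object@designedSiteCounts), collapse = ", "),
      "}\n", sep = "")
})

## ---------------------------------------------------------------------------
## Control selection / dedup / restriction filter / padding
## ---------------------------------------------------------------------------

#' Select control sgRNAs for assembly
#'
#' Negatives are drawn uniformly without replacement from the negative
#' library. Positives are drawn per request `(editor, outcome, n)` from
#' guides whose pick-isoform aggregated outcome matches; a guide selected
#' for one request is excluded from subsequent ones (non-overlapping).
#' All draws are seeded and reproducible.
#'
#' @param negativeTable,positiveTable [LibraryTable-class] objects (either
#'   may be `NULL`).
#' @param nNegative Number of negative controls to select.
#' @param positiveRequests List of `list(editor=, outcome=, n=)` requests.
#' @param seed Integer seed.
#' @return List with `negatives` and `positives` core-table `data.frame`s.
#' @export
selectControls <- function(negativeTable = NULL, positiveTable = NULL,
                           nNegative = 0L, positiveRequests = list(),
                           seed = 1L) {
  .withSeed(seed, {
    negatives <- NULL
    if (nNegative > 0L) {
      if (is.null(negativeTable)) .stopf("no negative library supplied")
      core <- negativeTable@core
      if (nrow(core) < nNegative) {
        .stopf("requested %d negative controls but only %d available",
               nNegative, nrow(core))
      }
      negatives <- core[sample.int(nrow(core), nNegative), , drop = FALSE]
    }
    positives <- NULL
    if (length(positiveRequests)) {
      if (is.null(positiveTable)) .stopf("no positive library supplied")
      taken <- character(0)
      sel <- list()
      for (req in positiveRequests) {
        blk <- positiveTable@annotations[[req$editor]]
        if (is.null(blk)) {
          .stopf("positive library has no annotation block for editor '%s'",
                 req$editor)
        }
        cand <- blk$guide_id[blk$aggregated_outcome == req$outcome]
        cand <- base::setdiff(cand, taken)
        if (length(cand) < req$n) {
          .stopf("positive-control shortfall for %s/%s: requested %d, available %d",
                 req$editor, req$outcome, req$n, length(cand))
        }
        pick <- sample(cand, req$n)
        taken <- c(taken, pick)
        sel[[length(sel) + 1L]] <- positiveTable@core[
          match(pick, positiveTable@core$guide_id), , drop = FALSE]
      }
      positives <- do.call(rbind, sel)
    }
    list(negatives = negatives, positives = positives)
  })
}

#' Remove duplicate sgRNAs
#'
#' Uniqueness is keyed on the protospacer sequence. The retained copy is the
#' first in precedence order target > positive > negative, then input order;
#' dropped rows are logged with the retained twin's id.
#'
#' @param guides Core-table `data.frame` with `protospacer`, `guide_id`,
#'   `library_type` columns.
#' @return List with `unique` and `dropped` data.frames (`dropped` has a
#'   `kept_twin` column).
#' @export
deduplicateGuides <- function(guides) {
  prec <- match(guides$library_type, c("target", "positive", "negative"))
  ord <- order(prec, seq_len(nrow(guides)))
  g <- guides[ord, , drop = FALSE]
  keep <- !duplicated(g$protospacer)
  uniq <- g[keep, , drop = FALSE]
  dropped <- g[!keep, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$kept_twin <- uniq$guide_id[match(dropped$protospacer,
                                             uniq$protospacer)]
  } else {
    dropped$kept_twin <- character(0)
  }
  ## restore input order within the kept set
  uniq <- uniq[order(match(uniq$guide_id, guides$guide_id)), , drop = FALSE]
  rownames(uniq) <- NULL
  rownames(dropped) <- NULL
  list(unique = uniq, dropped = dropped)
}

#' Filter guides whose spacer creates or reconstitutes restriction sites
#'
#' A guide is removed iff placing its spacer into any slot of the template
#' (site-free dummy spacers elsewhere) yields a recognition-site count, on
#' either strand, beyond the template's designed count -- covering sites
#' wholly inside the spacer and sites reconstituted across spacer/linker
#' junctions. Every slot is probed because linkers differ per slot and slot
#' assignment happens later.
#'
#' @param guides Core-table `data.frame` with `protospacer` and `guide_id`.
#' @param template An [OligomerTemplate-class].
#' @return List with `kept`, `removed` data.frames and a `reasons` log.
#' @export
filterRestrictionSites <- function(guides, template) {
  bad <- logical(nrow(guides))
  why <- character(nrow(guides))
  for (i in seq_len(nrow(guides))) {
    sp <- guides$protospacer[i]
    for (slot in seq_len(template@k)) {
      spacers <- rep(.DUMMY_SPACER, template@k)
      spacers[slot] <- sp
      oligo <- .buildOligomer(template, spacers)
      for (e in template@enzymes) {
        cnt <- countEnzymeSites(oligo, e)
        if (cnt > template@designedSiteCounts[[e]]) {
          bad[i] <- TRUE
          why[i] <- sprintf("extra %s site in slot %d (%d > %d designed)",
                            e, slot, cnt, template@designedSiteCounts[[e]])
          break
        }
      }
      if (bad[i]) break
    }
  }
  list(kept = guides[!bad, , drop = FALSE],
       removed = guides[bad, , drop = FALSE],
       reasons = data.frame(guide_id = guides$guide_id[bad],
                            reason = why[bad], stringsAsFactors = FALSE))
}

#' Pad the library to a multiple of k
#'
#' The deficit is filled first from unused negative controls, then unused
#' positive controls (seeded random draws); if the pools are exhausted,
#' target sgRNAs are removed at random until the count is a multiple of `k`.
#' Every change is reported.
#'
#' @param selected Combined core-table `data.frame` (targets + selected
#'   controls).
#' @param negativesPool,positivesPool Unused pool `data.frame`s (may be
#'   `NULL` or empty).
#' @param k sgRNAs per oligomer.
#' @param seed Integer seed.
#' @return List with `final` data.frame (`nrow %% k == 0`) and `report`
#'   data.frame of added/removed guide ids.
#' @export
padToMultiple <- function(selected, negativesPool = NULL,
                          positivesPool = NULL, k = 3L, seed = 1L) {
  if (k < 1L) .stopf("k must be >= 1")
  .withSeed(seed, {
    report <- data.frame(action = character(), guide_id = character(),
                         library_type = character(), stringsAsFactors = FALSE)
    final <- selected
    deficit <- (k - nrow(final) %% k) %% k
    if (deficit > 0L) {
      added <- 0L
      for (pool in list(negativesPool, positivesPool)) {
        want <- deficit - added
        if (want == 0L || is.null(pool) || nrow(pool) == 0L) next
        take <- pool[sample.int(nrow(pool), min(want, nrow(pool))), ,
                     drop = FALSE]
        final <- rbind(final, take[, colnames(final), drop = FALSE])
        report <- rbind(report, data.frame(action = "added",
                                           guide_id = take$guide_id,
                                           library_type = take$library_type,
                                           stringsAsFactors = FALSE))
        added <- added + nrow(take)
      }
      remainder <- nrow(final) %% k
      if (remainder > 0L) {
        isTarget <- which(final$library_type == "target")
        dropIdx <- if (length(isTarget) >= remainder) {
          sample(isTarget, remainder)
        } else {
          sample(seq_len(nrow(final)), remainder)
        }
        report <- rbind(report, data.frame(action = "removed",
                                           guide_id = final$guide_id[dropIdx],
                                           library_type = final$library_type[dropIdx],
                                           stringsAsFactors = FALSE))
        final <- final[-dropIdx, , drop = FALSE]
      }
    }
    rownames(final) <- NULL
    list(final = final, report = report)
  })
}

## ---------------------------------------------------------------------------
## Assembly
## ---------------------------------------------------------------------------

#' Assemble guides into multiplexed golden-gate oligomers
#'
#' Guides are shuffled (seeded) and partitioned into consecutive groups of
#' `k`; each group is instantiated into the template in slot order. Every
#' guide appears in exactly one oligomer, exactly once, and all oligomers of
#' a library have identical length.
#'
#' @param finalGuides Core-table `data.frame`, `nrow %% k == 0`, all guides
#'   already restriction-filtered.
#' @param template An [OligomerTemplate-class].
#' @param seed Integer seed.
#' @return List with `oligos` (`oligo_id`, `sequence`, `members`,
#'   `primer_pair`) and `slots` (`oligo_id`, `slot`, `guide_id`,
#'   `protospacer`) data.frames.
#' @export
assembleOligomers <- function(finalGuides, template, seed = 1L) {
  n <- nrow(finalGuides)
  if (n %% template@k != 0L) {
    .stopf("number of guides (%d) is not a multiple of k=%d", n, template@k)
  }
  .withSeed(seed, {
    shuffled <- finalGuides[sample.int(n), , drop = FALSE]
    nOligo <- n %/% template@k
    oligos <- vector("list", nOligo)
    slots <- vector("list", nOligo)
    for (i in seq_len(nOligo)) {
      rows <- shuffled[((i - 1L) * template@k + 1L):(i * template@k), ,
                       drop = FALSE]
      oid <- sprintf("oligo_%04d", i)
      oligos[[i]] <- data.frame(
        oligo_id = oid,
        sequence = .buildOligomer(template, rows$protospacer),
        members = paste(rows$guide_id, collapse = ";"),
        primer_pair = template@primerPairLabel,
        stringsAsFactors = FALSE)
      slots[[i]] <- data.frame(oligo_id = oid, slot = seq_len(template@k),
                               guide_id = rows$guide_id,
                               protospacer = rows$protospacer,
                               stringsAsFactors = FALSE)
    }
    list(oligos = do.call(rbind, oligos), slots = do.call(rbind, slots))
  })
}

#' Assemble one sensor oligonucleotide per guide
#'
#' The sensor is the genomic window around the guide's target site
#' (protospacer-strand orientation, default 7+20+3+10 = 40 nt). Guides too
#' close to a chromosome end for a full sensor are dropped with a warning;
#' oligos with BsmBI or EcoRI sites beyond the template's designed counts
#' are eliminated.
#'
#' @param finalGuides Core-table `data.frame` with coordinates and strand.
#' @param template A [SensorTemplate-class].
#' @param genome A [GenomeAssembly-class].
#' @return List with `oligos` (`oligo_id`, `guide_id`, `sequence`, `sensor`)
#'   and `removed` (guide ids with reasons) data.frames.
#' @export
assembleSensorOligos <- function(finalGuides, template, genome) {
  lens <- chromLengths(genome)
  oligos <- list()
  removed <- list()
  dropped <- 0L
  for (i in seq_len(nrow(finalGuides))) {
    g <- finalGuides[i, ]
    if (g$strand == "+") { lo <- g$start - template@upstreamNt
                           hi <- g$end + 3L + template@downstreamNt }
    else { lo <- g$start - 3L - template@downstreamNt
           hi <- g$end + template@upstreamNt }
    if (lo < 1L || hi > lens[[g$chrom]]) {
      dropped <- dropped + 1L
      removed[[length(removed) + 1L]] <- data.frame(
        guide_id = g$guide_id, reason = "sensor window outside chromosome",
        stringsAsFactors = FALSE)
      next
    }
    sensor <- .genomeSubseq(genome, g$chrom, lo, hi, g$strand)
    seqO <- .buildSensorOligo(template, g$protospacer, sensor)
    extra <- FALSE
    for (e in c("BsmBI", "EcoRI")) {
      if (countEnzymeSites(seqO, e) > template@designedSiteCounts[[e]]) {
        extra <- TRUE
        removed[[length(removed) + 1L]] <- data.frame(
          guide_id = g$guide_id,
          reason = sprintf("additional %s site in sensor oligo", e),
          stringsAsFactors = FALSE)
        break
      }
    }
    if (extra) next
    oligos[[length(oligos) + 1L]] <- data.frame(
      oligo_id = sprintf("sensor_%04d", length(oligos) + 1L),
      guide_id = g$guide_id, sequence = seqO, sensor = sensor,
      stringsAsFactors = FALSE)
  }
  if (dropped > 0L) {
    .warnf("%d guide(s) dropped: sensor window outside chromosome", dropped)
  }
  list(oligos = if (length(oligos)) do.call(rbind, oligos)
                else data.frame(oligo_id = character(), guide_id = character(),
                                sequence = character(), sensor = character()),
       removed = if (length(removed)) do.call(rbind, removed)
                 else data.frame(guide_id = character(), reason = character()))
}

#' Write the oligonucleotide order file
#'
#' One oligonucleotide sequence (5'->3') per line, ready for synthesis
#' ordering.
#'
#' @param oligos `data.frame` with a `sequence` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeOrderFile <- function(oligos, path) {
  writeLines(oligos$sequence, path)
  invisible(path)
}

#' Write the prepared-library manifest
#'
#' One row per sgRNA retained in the final assembly, with library type,
#' oligomer id and slot position -- the file downstream screen analyses key
#' on.
#'
#' @param finalGuides Final core-table `data.frame`.
#' @param slots Slot assignment `data.frame` from [assembleOligomers()] (or
#'   `NULL` for sensor mode, where each guide has its own oligo).
#' @param path Output CSV path.
#' @return The manifest `data.frame`, invisibly.
#' @export
writePreparedLibrary <- function(finalGuides, slots, path) {
  manifest <- finalGuides
  if (!is.null(slots)) {
    idx <- match(manifest$guide_id, slots$guide_id)
    manifest$oligo_id <- slots$oligo_id[idx]
    manifest$slot <- slots$slot[idx]
  }
  write.csv(manifest, path, row.names = FALSE)
  invisible(manifest)
}
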