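## Per-guide x per-editor mutational outcome prediction: construct the
## maximally edited allele inside the activity window, classify it against
## every overlapping transcript, aggregate to the five outcome classes
## (splice, nonsense, missense, synonymous, noncoding) plus no_edit.

.OUTCOME_SEVERITY <- c(splice = 5, nonsense = 4, missense = 3,
                       synonymous = 2, noncoding = 1)

#' Predicted edit of one guide under one base editor
#'
#' @slot guideId Guide identifier.
#' @slot editorName Editor name.
#' @slot substitutions `data.frame` with columns `chrom`, `pos` (1-based
#'   genomic), `ref`, `alt` -- alleles on the reference (+) strand.
#' @slot nEditedBases Number of substituted bases.
#' @slot perTranscript Per-transcript consequence table (filled by
#'   [annotateConsequence()]).
#' @slot aggregatedOutcome One of splice/nonsense/missense/synonymous/
#'   noncoding/no_edit (filled by [aggregateOutcome()]).
#' @export
setClass("PredictedEdit",
  representation(guideId = "character", editorName = "character",
                 substitutions = "data.frame", nEditedBases = "integer",
                 perTranscript = "data.frame",
                 aggregatedOutcome = "character"))

setMethod("show", "PredictedEdit", function(object) {
  cat("PredictedEdit ", object@guideId, " x ", object@editorName, ": ",
      object@nEditedBases, " base(s) edited",
      if (length(object@aggregatedOutcome))
        paste0(" -> ", object@aggregatedOutcome) else "", "\n", sep = "")
})

#' Enumerate the maximally edited allele of a guide under a base editor
#'
#' Every occurrence of the editor's reference base at protospacer positions
#' `windowStart..windowEnd` (1-based from the 5', PAM-distal end) is
#' substituted simultaneously -- one combined multi-base allele, not
#' per-base variants. With `excludeGC`, a C immediately preceded by G on the
#' protospacer strand is left unedited (for window position 1 the preceding
#' genomic base on the protospacer strand is consulted). Substitutions are
#' reported on the reference strand (complemented for minus-strand guides).
#' A window with no editable base yields `aggregatedOutcome = "no_edit"`.
#'
#' @param guide Single-element guide `GRanges`.
#' @param editor A [BaseEditor-class].
#' @param genome A [GenomeAssembly-class].
#' @return A [PredictedEdit-class].
#' @export
enumerateEdits <- function(guide, editor, genome) {
  proto <- S4Vectors::mcols(guide)$protospacer
  b <- strsplit(proto, "")[[1]]
  if (editor@windowEnd > length(b)) {
    .stopf("editor window end %d exceeds protospacer length %d",
           editor@windowEnd, length(b))
  }
  ch <- as.character(GenomicRanges::seqnames(guide))
  st <- GenomicRanges::start(guide)
  en <- GenomicRanges::end(guide)
  sd <- as.character(GenomicRanges::strand(guide))
  lens <- chromLengths(genome)

  win <- editor@windowStart:editor@windowEnd
  editable <- win[b[win] == editor@refBase]

  if (editor@excludeGC && editor@refBase == "C" && length(editable)) {
    precededByG <- vapply(editable, function(w) {
      if (w > 1L) return(b[w - 1L] == "G")
      ## position 1: consult the adjacent genomic base on the protospacer strand
      if (sd == "+") {
        if (st - 1L < 1L) return(FALSE)
        .genomeSubseq(genome, ch, st - 1L, st - 1L, "+") == "G"
      } else {
        if (en + 1L > lens[ch]) return(FALSE)
        .genomeSubseq(genome, ch, en + 1L, en + 1L, "-") == "G"
      }
    }, logical(1))
    editable <- editable[!precededByG]
  }

  if (length(editable) == 0L) {
    subs <- data.frame(chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       stringsAsFactors = FALSE)
  } else {
    gpos <- if (sd == "+") st + editable - 1L else en - editable + 1L
    ref <- if (sd == "+") rep(editor@refBase, length(editable))
           else unname(.complementBase(rep(editor@refBase, length(editable))))
    alt <- if (sd == "+") rep(editor@altBase, length(editable))
           else unname(.complementBase(rep(editor@altBase, length(editable))))
    ## corruption guard: reference alleles must match the genome
    gref <- vapply(gpos, function(p) .genomeSubseq(genome, ch, p, p, "+"), "")
    if (!all(gref == ref)) .stopf("reference allele mismatch at %s:%d",
                                  ch, gpos[which(gref != ref)[1]])
    ord <- order(gpos)
    subs <- data.frame(chrom = ch, pos = gpos[ord], ref = ref[ord],
                       alt = alt[ord], stringsAsFactors = FALSE)
  }
  new("PredictedEdit",
      guideId = S4Vectors::mcols(guide)$guide_id,
      editorName = editor@name,
      substitutions = subs,
      nEditedBases = nrow(subs),
      perTranscript = data.frame(),
      aggregatedOutcome = if (nrow(subs) == 0L) "no_edit" else character(0))
}

## Map genomic positions to spliced CDS coordinates (1-based, coding strand).
## Returns NA for positions outside the CDS.
.cdsCoord <- function(tx, gpos) {
  if (length(tx@cds) == 0L) return(rep(NA_integer_, length(gpos)))
  st <- IRanges::start(tx@cds)
  en <- IRanges::end(tx@cds)
  w <- IRanges::width(tx@cds)
  offs <- cumsum(c(0L, w[-length(w)]))
  total <- sum(w)
  vapply(gpos, function(p) {
    k <- which(p >= st & p <= en)
    if (length(k) == 0L) return(NA_integer_)
    plusPos <- offs[k] + (p - st[k]) + 1L
    if (tx@strand == "+") plusPos else total - plusPos + 1L
  }, integer(1))
}

#' Classify a predicted edit against overlapping transcripts
#'
#' For each transcript whose exons (with an 8-nt intronic flank) overlap any
#' substitution: a substitution in the 2 intronic nt adjacent to an exon
#' boundary (splice donor/acceptor positions) is `splice`; substitutions in
#' the CDS are classified by retranslating the affected codons -- stop gained
#' or start codon lost is `nonsense`, an amino-acid change `missense`, a
#' silent CDS change `synonymous`; substitutions only in UTR or non-splice
#' intron are `noncoding`. A transcript may accumulate several classes
#' (all are recorded).
#'
#' @param edit A [PredictedEdit-class].
#' @param transcripts Named list of [TranscriptModel-class].
#' @param genome A [GenomeAssembly-class].
#' @return `data.frame` with one row per overlapping transcript: columns
#'   `transcript_id`, `gene_name`, `consequences` (comma-joined classes),
#'   `is_canonical`.
#' @export
annotateConsequence <- function(edit, transcripts, genome) {
  subs <- edit@substitutions
  empty <- data.frame(transcript_id = character(), gene_name = character(),
                      consequences = character(), is_canonical = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(subs) == 0L) return(empty)
  ## corruption guard
  for (i in seq_len(nrow(subs))) {
    if (.genomeSubseq(genome, subs$chrom[i], subs$pos[i], subs$pos[i], "+") !=
        subs$ref[i]) {
      .stopf("substitution ref allele mismatch with genome at %s:%d",
             subs$chrom[i], subs$pos[i])
    }
  }
  rows <- list()
  for (tx in transcripts) {
    if (tx@chrom != subs$chrom[1]) next
    exSt <- IRanges::start(tx@exons)
    exEn <- IRanges::end(tx@exons)
    nearExon <- vapply(subs$pos, function(p) {
      any(p >= exSt - 8L & p <= exEn + 8L)
    }, logical(1))
    if (!any(nearExon)) next

    ## splice donor/acceptor: the 2 intronic nt flanking each exon boundary
    splicePos <- integer(0)
    if (length(tx@exons) > 1L) {
      for (k in seq_len(length(tx@exons) - 1L)) {
        is <- exEn[k] + 1L
        ie <- exSt[k + 1L] - 1L
        splicePos <- c(splicePos, is, is + 1L, ie - 1L, ie)
      }
    }
    classes <- character(0)
    cdsSeq <- cdsSequence(genome, tx)
    cdsIdx <- .cdsCoord(tx, subs$pos)
    inExon <- vapply(subs$pos, function(p) any(p >= exSt & p <= exEn),
                     logical(1))

    ## codon-level retranslation of affected codons
    codingSubs <- which(!is.na(cdsIdx))
    if (length(codingSubs)) {
      codonIdx <- (cdsIdx[codingSubs] - 1L) %/% 3L + 1L
      for (ci in unique(codonIdx)) {
        inCodon <- codingSubs[codonIdx == ci]
        refCodon <- substring(cdsSeq, (ci - 1L) * 3L + 1L, ci * 3L)
        mutC <- strsplit(refCodon, "")[[1]]
        for (s in inCodon) {
          within <- cdsIdx[s] - (ci - 1L) * 3L
          altCoding <- if (tx@strand == "+") subs$alt[s]
                       else unname(.complementBase(subs$alt[s]))
          mutC[within] <- altCoding
        }
        mutCodon <- paste(mutC, collapse = "")
        refAA <- as.character(Biostrings::GENETIC_CODE[refCodon])
        mutAA <- as.character(Biostrings::GENETIC_CODE[mutCodon])
        if (ci == 1L && refCodon == "ATG" && mutCodon != "ATG") {
          classes <- c(classes, "nonsense")      # start codon lost
        } else if (mutAA == "*" && refAA != "*") {
          classes <- c(classes, "nonsense")      # stop gained
        } else if (mutAA != refAA) {
          classes <- c(classes, "missense")
        } else {
          classes <- c(classes, "synonymous")
        }
      }
    }
    if (any(subs$pos %in% splicePos)) classes <- c(classes, "splice")
    nonCoding <- which(is.na(cdsIdx) & !(subs$pos %in% splicePos) & nearExon)
    if (length(nonCoding)) classes <- c(classes, "noncoding")

    if (length(classes) == 0L) next
    classes <- unique(classes)
    classes <- classes[order(-.OUTCOME_SEVERITY[classes])]
    rows[[tx@transcriptId]] <- data.frame(
      transcript_id = tx@transcriptId, gene_name = tx@geneName,
      consequences = paste(classes, collapse = ","),
      is_canonical = tx@isCanonical, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Aggregate per-transcript consequences to a single outcome
#'
#' Applies the severity order splice > nonsense > missense > synonymous >
#' noncoding within one picked transcript. The default pick rule selects the
#' canonical transcript when it overlaps the edit, else the overlapping
#' transcript with the longest CDS (a stand-in for VEP's `--pick` ordering;
#' ties broken by lexicographic transcript id). Edits overlapping no
#' transcript are `noncoding`; `no_edit` passes through upstream.
#'
#' @param perTranscript Output of [annotateConsequence()].
#' @param transcripts Named list of [TranscriptModel-class] (for CDS lengths).
#' @return List with `outcome`, `pick_transcript`, `pick_is_canonical`.
#' @export
aggregateOutcome <- function(perTranscript, transcripts) {
  if (nrow(perTranscript) == 0L) {
    return(list(outcome = "noncoding", pick_transcript = NA_character_,
                pick_is_canonical = NA))
  }
  ids <- perTranscript$transcript_id
  pick <- if (any(perTranscript$is_canonical)) {
    ids[perTranscript$is_canonical][1]
  } else {
    w <- vapply(ids, function(id) sum(IRanges::width(transcripts[[id]]@cds)), 0)
    ids[order(-w, ids)][1]
  }
  classes <- strsplit(
    perTranscript$consequences[perTranscript$transcript_id == pick], ",")[[1]]
  list(outcome = names(which.max(.OUTCOME_SEVERITY[classes])),
       pick_transcript = pick,
       pick_is_canonical = perTranscript$is_canonical[
         perTranscript$transcript_id == pick])
}

## HGVS-like g. string for a substitution set
.hgvsG <- function(subs) {
  if (nrow(subs) == 0L) return(NA_character_)
  paste0(subs$chrom[1], ":",
         paste(sprintf("g.%d%s>%s", subs$pos, subs$ref, subs$alt),
               collapse = ";"))
}

## Shared key for guides inserting the same variant
.variantKey <- function(subs) {
  if (nrow(subs) == 0L) return(NA_character_)
  paste(sprintf("%s:%d:%s>%s", subs$chrom, subs$pos, subs$ref, subs$alt),
        collapse = "|")
}

#' Annotate a guide library with predicted outcomes for each editor
#'
#' Runs [enumerateEdits()], [annotateConsequence()] and [aggregateOutcome()]
#' for every guide x editor pair and assembles a [LibraryTable-class]:
#' the core guide table plus one annotation block per editor. Guides
#' producing identical substitution sets share a `variant_key`.
#'
#' @param guides Guide `GRanges` (off-target/on-target columns included if
#'   present).
#' @param editors List of [BaseEditor-class] objects (at least one).
#' @param genome A [GenomeAssembly-class].
#' @param transcripts Named list of [TranscriptModel-class].
#' @param libraryType Library type recorded on the table
#'   (`"target"`, `"positive"`, `"negative"`).
#' @return A [LibraryTable-class].
#' @export
annotateLibrary <- function(guides, editors, genome, transcripts,
                            libraryType = "target") {
  if (length(editors) == 0L) .stopf("at least one base editor is required")
  core <- guidesToDataFrame(guides)
  extra <- S4Vectors::mcols(guides)
  for (col in c("n_offtargets", "max_offtarget_cfd", "on_target_score")) {
    if (col %in% colnames(extra)) core[[col]] <- extra[[col]]
  }
  blocks <- list()
  for (ed in editors) {
    rows <- lapply(seq_along(guides), function(i) {
      edit <- enumerateEdits(guides[i], ed, genome)
      pt <- annotateConsequence(edit, transcripts, genome)
      outcome <- if (edit@nEditedBases == 0L) {
        list(outcome = "no_edit", pick_transcript = NA_character_,
             pick_is_canonical = NA)
      } else aggregateOutcome(pt, transcripts)
      data.frame(
        guide_id = edit@guideId,
        editor = ed@name,
        substitutions = .hgvsG(edit@substitutions),
        n_edited_bases = edit@nEditedBases,
        variant_key = .variantKey(edit@substitutions),
        per_isoform = if (nrow(pt)) {
          paste(sprintf("%s%s:%s", pt$transcript_id,
                        ifelse(pt$is_canonical, "[canonical]", ""),
                        pt$consequences), collapse = ";")
        } else NA_character_,
        pick_transcript = outcome$pick_transcript,
        pick_is_canonical = outcome$pick_is_canonical,
        aggregated_outcome = outcome$outcome,
        stringsAsFactors = FALSE)
    })
    blocks[[ed@name]] <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  LibraryTable(core, blocks, libraryType)
}
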