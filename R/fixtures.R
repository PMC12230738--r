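## Seeded synthetic genome + annotation generator used by tests, examples and
## the acceptance workflow. Emulates compact eukaryote-like loci:
## multi-isoform genes (shared first exon, one exon-skipping isoform, small
## UTRs, introns), a designated essential-gene locus for positive controls,
## a gene-free safe-harbor locus for negative controls, and a blacklist
## interval. It does not emulate repeat content, chromatin or real codon
## usage; see the methods vignette.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.randomCodons <- function(n) {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  pool <- base::setdiff(all64, .STOP_CODONS)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

## Build one gene cassette (coding-strand layout) with two isoforms:
## t1 = exon1+exon2+exon3, t2 skips exon2 (frame preserved: codon-aligned
## exon boundaries). Returns relative 1-based coordinates within the cassette.
.makeGeneCassette <- function() {
  u5 <- 10L + sample.int(8L, 1L)            # 5' UTR
  a <- 4L + sample.int(6L, 1L)              # codons in exon1 after ATG
  b <- 4L + sample.int(6L, 1L)              # codons in exon2
  cc <- 4L + sample.int(6L, 1L)             # codons in exon3 before stop
  u3 <- 10L + sample.int(8L, 1L)            # 3' UTR
  i1 <- 30L + sample.int(20L, 1L)
  i2 <- 30L + sample.int(20L, 1L)

  exon1 <- paste0(.randomDna(u5), "ATG", .randomCodons(a))
  exon2 <- .randomCodons(b)
  stopC <- sample(.STOP_CODONS, 1L)
  exon3 <- paste0(.randomCodons(cc), stopC, .randomDna(u3))
  intron1 <- paste0("GT", .randomDna(i1 - 4L), "AG")
  intron2 <- paste0("GT", .randomDna(i2 - 4L), "AG")

  seq <- paste0(exon1, intron1, exon2, intron2, exon3)
  e1 <- c(1L, nchar(exon1))
  e2 <- c(e1[2] + nchar(intron1) + 1L, e1[2] + nchar(intron1) + nchar(exon2))
  e3 <- c(e2[2] + nchar(intron2) + 1L, e2[2] + nchar(intron2) + nchar(exon3))
  cds1s <- u5 + 1L                          # ATG start within exon1
  cds3e <- e3[1] + cc * 3L + 2L             # end of stop codon within exon3
  list(
    seq = seq,
    exons_t1 = list(e1, e2, e3),
    exons_t2 = list(e1, e3),
    cds_t1 = list(c(cds1s, e1[2]), e2, c(e3[1], cds3e)),
    cds_t2 = list(c(cds1s, e1[2]), c(e3[1], cds3e))
  )
}

## Map a relative interval to genomic coordinates given cassette placement.
.placeIv <- function(iv, offset, len, strand) {
  if (strand == "+") c(offset + iv[1] - 1L, offset + iv[2] - 1L)
  else c(offset + len - iv[2], offset + len - iv[1])
}

#' Generate a deterministic synthetic genome, annotation and blacklist
#'
#' Writes a toy FASTA genome, a GFF3 annotation and a blacklist BED into
#' `dir`. Chromosome `chr1` carries `nGenes` two-isoform genes (one on the
#' minus strand when `nGenes >= 2`); chromosome `chrE` carries a designated
#' essential gene (`ESS1`) for positive-control design; chromosome `chrS` is
#' a gene-free safe-harbor locus for negative-control design. Every
#' generated transcript passes [loadAnnotation()] validation, and every CDS
#' translates to `M...` with a terminal stop and no internal stop. Output is
#' byte-identical for a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; all randomness derives from it.
#' @param nGenes Number of genes on `chr1` (default 3).
#' @param chromLength Length of `chr1` in nt (default 6000).
#' @return List with `fasta`, `gff3`, `blacklist` file paths plus
#'   `safeHarborRegion` (a region string) and `essentialGene` (`"ESS1"`).
#' @examples
#' fx <- generateFixture(tempfile("fx"), seed = 1)
#' genome <- loadGenome(fx$fasta)
#' @export
generateFixture <- function(dir, seed, nGenes = 3L, chromLength = 6000L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nGenes <- as.integer(nGenes)
  chromLength <- as.integer(chromLength)
  spacing <- (chromLength - 700L) %/% nGenes
  if (spacing < 400L) .stopf("chromLength too small for %d genes", nGenes)

  .withSeed(seed, {
    gff <- c("##gff-version 3")
    geneRecords <- list()

    emitGene <- function(geneName, chrom, offset, strand, canonicalTag = TRUE) {
      cas <- .makeGeneCassette()
      len <- nchar(cas$seq)
      placed <- if (strand == "+") cas$seq else .revcomp(cas$seq)
      gstart <- offset
      gend <- offset + len - 1L
      lines <- c(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                         chrom, "beTilerFixture", gstart, gend, strand,
                         geneName, geneName))
      for (iso in c("t1", "t2")) {
        txId <- paste0(geneName, ".", iso)
        exKey <- paste0("exons_", iso)
        cdsKey <- paste0("cds_", iso)
        exG <- lapply(cas[[exKey]], .placeIv, offset = offset, len = len,
                      strand = strand)
        cdsG <- lapply(cas[[cdsKey]], .placeIv, offset = offset, len = len,
                       strand = strand)
        ord <- order(vapply(exG, `[`, 0L, 1L))
        exG <- exG[ord]
        cdsG <- cdsG[order(vapply(cdsG, `[`, 0L, 1L))]
        attr <- sprintf("ID=%s;Parent=%s;Name=%s", txId, geneName, txId)
        if (iso == "t1" && canonicalTag) {
          attr <- paste0(attr, ";tag=Ensembl_canonical")
        }
        lines <- c(lines,
          sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\t%s",
                  chrom, "beTilerFixture",
                  min(vapply(exG, `[`, 0L, 1L)),
                  max(vapply(exG, `[`, 0L, 2L)), strand, attr))
        for (e in exG) {
          lines <- c(lines,
            sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                    chrom, "beTilerFixture", e[1], e[2], strand, txId))
        }
        for (cd in cdsG) {
          lines <- c(lines,
            sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                    chrom, "beTilerFixture", cd[1], cd[2], strand, txId))
        }
      }
      list(seq = placed, start = gstart, end = gend, gff = lines)
    }

    ## --- chr1: nGenes genes, gene 2 on the minus strand ---
    chr1 <- character(0)
    cursor <- 1L
    for (i in seq_len(nGenes)) {
      offset <- 200L + (i - 1L) * spacing
      strand <- if (i == 2L && nGenes >= 2L) "-" else "+"
      g <- emitGene(sprintf("GENE%d", i), "chr1", offset, strand)
      chr1 <- c(chr1, .randomDna(offset - cursor), g$seq)
      cursor <- g$end + 1L
      gff <- c(gff, g$gff)
    }
    chr1 <- paste0(paste(chr1, collapse = ""),
                   .randomDna(chromLength - cursor + 1L))

    ## --- chrE: essential gene locus ---
    eg <- emitGene("ESS1", "chrE", 151L, "+")
    chrE <- paste0(.randomDna(150L), eg$seq, .randomDna(200L))
    gff <- c(gff, eg$gff)

    ## --- chrS: safe harbor, gene-free ---
    chrS <- .randomDna(1200L)

    fasta <- file.path(dir, "fixture_genome.fa")
    gff3 <- file.path(dir, "fixture_annotation.gff3")
    blacklist <- file.path(dir, "fixture_blacklist.bed")

    seqs <- Biostrings::DNAStringSet(c(chr1 = chr1, chrE = chrE, chrS = chrS))
    Biostrings::writeXStringSet(seqs, fasta, width = 80L)
    writeLines(gff, gff3)
    ## blacklist: an intergenic interval near the chr1 telomere
    writeLines(sprintf("chr1\t%d\t%d\tblacklist1",
                       chromLength - 150L, chromLength - 90L), blacklist)

    list(fasta = fasta, gff3 = gff3, blacklist = blacklist,
         safeHarborRegion = sprintf("chrS:%d-%d", 101L, 900L),
         essentialGene = "ESS1")
  })
}
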