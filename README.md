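# beTiler

**Design, annotate, and assemble sgRNA tiling libraries for CRISPR
base-editing screens.**

Base-editing (BE) screens interrogate point mutations *en masse*: a cytosine
or adenine base editor (CBE/ABE) installs C→T or A→G substitutions inside a
defined protospacer window, so every sgRNA corresponds to a predictable set
of point mutations. Designing such a screen means tiling every targetable
position of the features of interest with guides, predicting the mutational
outcome of each guide under each editor, filtering promiscuous guides, and
turning the final library into synthesizable DNA. beTiler implements this
whole path as an R package for screen designers:

1. **Target resolution** — gene names (via a GFF3 annotation) or genomic
   region strings are resolved into non-overlapping intervals, with
   per-entry flanks, optional restriction to canonical isoforms, and
   blacklist exclusion.
2. **Guide scanning** — both strands are scanned for protospacers adjacent
   to the Cas variant's PAM set (SpCas9 NGG; SpG NGG/NGA/NGC/NGT; SpRY NNN;
   user-definable).
3. **Off-target filtering** — exhaustive genome-wide enumeration of
   mismatch sites, scored with a variant-adjusted CFD scheme. The CFD score
   of an off-target site is

   `CFD = prod_{p=1..20} f(p, g_p, t_p) × f_PAM`

   where `f(p, g_p, t_p)` is the mismatch penalty for guide base `g_p`
   versus target base `t_p` at protospacer position `p` (position 1 =
   PAM-distal 5' end), and `f_PAM` is the PAM factor. The variant
   adjustment marks every PAM the Cas variant can use as 100% cutting
   efficiency (`f_PAM = 1`) and every other PAM as 0% — e.g. under SpG,
   NGG/NGA/NGC/NGT all score 1 and everything else scores 0. Guides
   exceeding a user threshold of scoring off-targets are removed.
4. **Outcome prediction** — for every guide × editor pair the maximally
   edited allele inside the activity window is constructed (optionally
   sparing Cs in GC motifs), classified per overlapping transcript by
   retranslating the affected codons, and aggregated to
   **splice > nonsense > missense > synonymous > noncoding** (plus
   `no_edit` for empty-window guides) on a picked isoform.
5. **Oligo assembly** — target + control libraries are merged,
   deduplicated on protospacer, filtered for created/reconstituted BsmBI
   (golden-gate) sites, padded to multiples of *k* guides per oligomer, and
   written as an order-ready oligo pool plus a `Prepared_library.csv`
   manifest — or as per-guide ~205-nt sensor oligos carrying a 40-nt copy of
   the genomic target site (BsmBI/EcoRI filtered).
6. **Reporting & QC** — per-gene guide counts, per-editor outcome
   breakdowns, BED/BedGraph coverage tracks, and a Gini-index utility for
   post-sequencing library uniformity.

A seeded synthetic-fixture generator (`generateFixture()`) builds toy
genomes with multi-isoform genes, an essential-gene locus and a safe-harbor
locus, so the entire pipeline can be exercised and tested without external
data.

## Worked example

```r
library(beTiler)

fx       <- generateFixture(tempfile("fx"), seed = 1)
genome   <- loadGenome(fx$fasta)
txs      <- loadAnnotation(fx$gff3, genome)
editors  <- list(baseEditorPreset("BE4"), baseEditorPreset("ABE8e"))
cas      <- casVariantPreset("SpCas9")

target <- designLibrary(genome, txs, c("GENE1", "GENE2", "GENE3"), cas,
                        editors, flankNt = 10,
                        blacklist = readBed(fx$blacklist))
target
#> LibraryTable (target): 86 sgRNA(s), 2 editor annotation block(s)

table(libraryAnnotations(target)$BE4$aggregated_outcome)
#>   missense    no_edit  noncoding   nonsense     splice synonymous
#>         14         12         40          7          3         10

negative <- designLibrary(genome, txs, fx$safeHarborRegion, cas, editors,
                          libraryType = "negative")
positive <- designLibrary(genome, txs, "ESS1", cas, editors, flankNt = 10,
                          libraryType = "positive")

res <- assembleLibrary(target, negative, positive, nNegative = 6,
         positiveRequests = list(list(editor = "BE4", outcome = "missense",
                                      n = 2)),
         seed = 7, outDir = "assembly")
res$audit
#>               input       dedup_dropped restriction_dropped
#>                  94                   0                   0
#>      sensor_dropped       padding_added     padding_removed
#>                   0                   2                   0
#>       manifest_rows
#>                  96
```

86 target guides plus 6 negative and 2 positive controls (94) were padded
with 2 extra negatives to reach 96 = 32 × 3 guides, assembled into 32
oligomers of 187 nt (3 sgRNAs each, 6 designed BsmBI sites per oligomer),
written to `assembly/oligo_order.txt` with the manifest in
`assembly/Prepared_library.csv`. Every count change is itemised in
`assembly/change_report.csv`.

The per-editor annotation blocks give, for each guide, the combined
substitution allele (HGVS-like `g.` string), the number of edited bases, a
variant key shared by guides inserting the same variant, per-isoform
consequences with canonical/pick flags, and the aggregated outcome.

A thin command-line front-end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","betiler.R",package="beTiler"))') \
  design --genes genes.txt --genome genome.fa --gff annotation.gff3 \
  --flank 10 --blacklist blacklist.bed --out design_out
```

## Package layout

- `R/` — implementation: genome/annotation model, fixture generator, guide
  scanning, off-target scoring, outcome prediction, oligo assembly,
  reporting.
- `inst/extdata/` — synthetic CFD mismatch-penalty table (see its header)
  and an example editor-definition YAML.
- `inst/cli/betiler.R` — command-line front-end.
- `vignettes/` — methods vignette describing the models, conventions and
  design decisions.
- `tests/testthat/` — unit, property and acceptance tests with independent
  oracles (naive rescans, double sums, full-CDS retranslation).
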