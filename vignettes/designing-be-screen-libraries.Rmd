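---
title: "Designing sgRNA tiling libraries for base-editing screens with beTiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing sgRNA tiling libraries for base-editing screens with beTiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beTiler)
```

## The problem

A base-editing (BE) screen installs point mutations *en masse*: a nickase
Cas9 fused to a cytosine or adenine deaminase converts C→T (or C→G) or A→G
within a defined window of the protospacer, so each sgRNA maps to a
predictable multi-base allele. Designing such a screen requires four linked
computations — tiling the features of interest with every targetable guide,
predicting each guide's mutational outcome under each editor, removing
guides likely to act elsewhere in the genome, and converting the final
library into synthesizable, clonable DNA. beTiler implements this pipeline
end to end; this vignette documents the models, conventions and numerical
choices behind each stage.

## Data model and coordinate conventions

Genomes are `GenomeAssembly` objects (a named `DNAStringSet`, uppercased,
alphabet A/C/G/T/N); transcripts are `TranscriptModel` objects with sorted,
non-overlapping exon intervals and CDS intervals contained in exons, CDS
length a multiple of 3. Internally all intervals are 1-based closed
`IRanges`/`GRanges`, the native Bioconductor convention; conversions happen
only at format boundaries — BED files are written/read 0-based half-open,
GFF3 and user-facing tables and region strings (`"chrom:start-end"`) are
1-based inclusive. Keeping a single internal convention, with conversions
confined to I/O, is what prevents off-by-one drift across five pipeline
stages. Guide identifiers embed 0-based half-open coordinates
(`chr1:100-120:+`) so they are reproducible from position alone, without
run-dependent counters.

When a GFF3 lacks canonical-isoform tags, the transcript with the longest
CDS per gene is flagged canonical, ties broken by lexicographic transcript
id — a deterministic local stand-in for an annotation-provided tag.

## Target resolution

Gene entries resolve to the union of CDS intervals across isoforms (or the
canonical isoform only), each extended by `flankNt` and merged per gene, so
every genomic base is targeted at most once regardless of how many isoforms
share it. Region entries are taken as given plus flanks. Two rules are
enforced strictly:

* **Cross-entry overlaps are an error**, not a merge — overlapping entries
  would silently design duplicate sgRNAs that the assembly step would then
  have to discard.
* **Blacklist intervals are trimmed away**, not used to drop whole regions:
  trimming preserves the maximal targetable sequence when a feature only
  brushes an excluded interval. A region entirely inside the blacklist is
  dropped with a warning.

The summed width of all resolved regions is capped (default 1.5 Mb,
configurable) as a guard against accidental genome-scale requests. The
flank default is 0 nt; flanks exist so that guides can fully mutate feature
boundaries such as splice sites.

## Guide scanning

Both strands are scanned for every position where a full-length protospacer
(default 20 nt, configurable per Cas variant) plus a 3′ PAM matching one of
the variant's IUPAC patterns fits inside the chromosome. A guide belongs to
a region if its protospacer overlaps it by ≥ 1 nt — the protospacer, not the
PAM, is what mutates, and the ≥ 1 nt rule keeps boundary bases reachable.
Protospacers containing N are dropped. Only 3′-PAM (Cas9-family)
architectures are supported; 5′-PAM variants are rejected with a clear
error rather than silently mis-scanned.

## Variant-adjusted CFD off-target scoring

Off-target sites are enumerated by exhaustive scan: every genomic window on
either strand with an allowed PAM and Hamming distance ≤ `maxMismatches`
(default 3, hard cap 4) from the protospacer. Each site is scored

$$\mathrm{CFD} = \prod_{p=1}^{20} f(p,\, g_p,\, t_p) \times f_{\mathrm{PAM}}$$

with position 1 the PAM-distal 5′ protospacer base and matched bases scoring
1. The adjustment for engineered Cas variants is conservative and exact:
every PAM the variant can use scores $f_{\mathrm{PAM}} = 1$ (100% cutting
efficiency) and every other PAM scores 0. Under SpG, NGG/NGA/NGC/NGT all
score 1; under SpCas9 only NGG does. Sites with disallowed PAMs are excluded
at enumeration time — mathematically identical to multiplying by a zero PAM
factor, but cheaper. Ambiguous (N) bases never match anything: a site
containing N scores 0.

A guide is removed when its count of off-target hits with
`cfd >= cfdThreshold` (default 0.2), excluding the on-target site itself
(identified by exact chromosome/interval/strand identity — the only
unambiguous rule), exceeds `maxOfftargets` (default 0). Filtering applies
only to SpCas9-family variants, since the CFD factors were calibrated on
SpCas9; other variants pass through with a warning. Both defaults are
exposed, and filtering is monotone in both thresholds by construction.

**The mismatch penalty table shipped with the package is synthetic.** The
published per-position CFD factors are not redistributable here, so
`inst/extdata/cfd_mismatch_penalties_synthetic.tsv` provides a deterministic
surrogate with the published table's structural properties: factors in
[0, 1], matches = 1, PAM-proximal mismatches penalised more
(`factor = tol × (1 − 0.75(p−1)/19)`), transitions (tol 0.60) and a
wobble-like guide-G/target-A pairing (tol 0.70) tolerated more than
transversions (tol 0.35). Any table with columns
`position/guide_base/offtarget_base/factor` can be dropped in via
`mismatchPenaltyMatrix(cas, tablePath=)`; the PAM factor vector — the part
that carries the variant adjustment — is always derived from the Cas
variant's PAM patterns and is exact regardless of the mismatch table.

On-target efficiency scoring is pluggable. Trained models are not bundled;
the default is a deterministic surrogate, labelled as such in the output
(`on_target_method = "surrogate"`), mapping the 30-nt context (4 nt
upstream + protospacer + PAM + 3 nt downstream) to [0, 1] via a Gaussian
GC-content preference (optimum 55%, sd 15%) with a 10% bonus for G at
protospacer position 20. Its only purposes are to exercise the interface
and provide a reproducible ranking on fixtures; any
`function(context) -> numeric` can replace it, and `scorer = NULL` leaves
the column empty without breaking the pipeline.

## Predicted mutational outcomes

For each guide × editor pair, **all** occurrences of the editor's reference
base within the activity window are substituted simultaneously — one
combined multi-base allele per pair, not per-base variants. This mirrors
how tiling-screen annotations are consumed downstream; position-weighted
partial-edit alleles are a known limitation, not modelled here. Window
positions are 1-based from the PAM-distal 5′ end (so BE4 ≈ 4–8), the
standard convention in the BE literature; it is stated here prominently
because editor definitions supplied in config must use it.

With `excludeGC = TRUE` (APOBEC-1 CBEs disfavour GC-motif editing), a C
immediately preceded by G **on the protospacer strand** is left unedited;
for window position 1 the adjacent genomic base on the protospacer strand
is consulted. The protospacer strand is the displaced strand the deaminase
acts on, which is why the motif is evaluated there rather than on the
reference strand; this is an interpretation the package documents rather
than a settled convention.

Substitutions are reported on the reference strand (complemented for
minus-strand guides) and validated against the genome — a mismatch is a
hard error, guarding against corrupted inputs. A guide with no editable
base in its window is classed `no_edit`; such empty-window guides are
useful internal negative controls and are reported as their own class.

Consequences are computed per overlapping transcript (exons ± 8 nt intronic
flank): a substitution in the 2 intronic nt adjacent to an exon boundary is
`splice` (the canonical GT/AG donor/acceptor positions only — broader
splice-region classes are not replicated); CDS substitutions are classified
by retranslating the affected codons — stop gained or start codon lost is
`nonsense`, an amino-acid change `missense`, a silent change `synonymous`;
everything else near the transcript is `noncoding`. One transcript can
accumulate several classes and all are recorded. Aggregation applies the
severity order **splice > nonsense > missense > synonymous > noncoding**
within a single picked isoform: the canonical transcript when it overlaps
the edit, else the overlapping transcript with the longest CDS (a local
stand-in for annotation-tool pick heuristics, flagged as such in the
output). Guides overlapping no transcript aggregate to `noncoding`. Guides
producing identical substitution sets share a `variant_key`, so redundant
alleles can be collapsed in analysis.

## Oligonucleotide assembly

Libraries are assembled for golden-gate cloning with the type IIS enzyme
BsmBI (recognition CGTCTC, cutting outside its site), so the one inviolable
constraint is that no assembled oligomer may contain BsmBI sites beyond the
designed ones. The shipped oligomer template (primers, per-slot linkers
with one opening and one closing BsmBI site each, 2k designed sites for k
slots) is an explicit structural placeholder: published cloning protocols
keep their exact linker sequences in their own supplements, and every
computational contract here — site counting on both strands, junction
reconstitution, fixed oligomer length — is independent of the particular
placeholder bases. Templates are fully config-driven.

The assembly pipeline is: merge target + seeded random control selections →
deduplicate on protospacer (precedence target > positive > negative, then
input order, so the screen's subject matter survives collisions) → filter
restriction sites → pad to a multiple of k → shuffle and partition into
oligomers. Restriction filtering tests each spacer **in every slot** (with
site-free dummy spacers elsewhere), because linkers differ per slot and
slot assignment happens only later; this catches both sites wholly inside a
spacer and sites reconstituted across spacer/linker junctions, and is
strictly conservative with respect to checking after assignment. Padding
fills the deficit first from unused negative controls, then unused
positives, and as a last resort removes target guides at random; every
added or removed guide id is itemised in the change report, and the
conservation identity

```
input − dedup_dropped − restriction_dropped − padding_removed + padding_added = manifest_rows
```

is checked on every run. One user-visible seed governs control selection,
padding and shuffling, making the order file byte-reproducible.

Sensor mode instead emits one ~205-nt oligo per guide: primer / BsmBI arm /
spacer / sgRNA scaffold / 40-nt sensor / EcoRI arm / primer, where the
sensor is the genomic window around the target site in protospacer
orientation, split 7 nt upstream + 20 protospacer + 3 PAM + 10 downstream —
a centring convention, configurable. Oligos with BsmBI or EcoRI sites
beyond the template's designed counts are eliminated; guides too close to a
chromosome end for a full sensor are dropped with a warning.

## The synthetic fixture generator

`generateFixture()` builds a deterministic toy genome: `chr1` with
multi-isoform genes (shared first exon, a frame-preserving exon-skipping
isoform, small UTRs, GT..AG introns, valid ATG...stop CDS with no internal
stops), `chrE` with a designated essential gene for positive-control
design, `chrS` as a gene-free safe-harbor locus for negatives, plus a
blacklist interval. Default dimensions (6 kb chr1, 3 genes, ~40–55 nt
introns, 4–10 codons per exon) keep full exhaustive off-target enumeration
and oracle re-scans fast while still exercising every code path: both
strands, isoform structure, splice sites, UTRs, blacklist trimming and
control selection. These sizes are the package's chosen test conditions,
stated here so results are interpretable.

What the fixture does **not** emulate: realistic genome size and k-mer
redundancy (off-target counts on real genomes are far higher), repeat
content, codon usage, GC structure, chromatin, or realistic intron/exon
length distributions. Passing tests therefore demonstrate correctness of
the algorithms — exact enumeration, classification, accounting,
determinism — not performance or guide-quality claims on mammalian genomes;
the exhaustive off-target scan in particular is intended for fixture-scale
genomes, with index-based search out of scope.

## Numerical choices and degenerate inputs

* Off-target defaults: `maxMismatches = 3`, `cfdThreshold = 0.2`,
  `maxOfftargets = 0` — exposed, not hard-coded.
* Ties: canonical fallback and pick rule break ties by lexicographic
  transcript id; deduplication keeps the first copy in precedence-then-input
  order. All tie-breaks are deterministic.
* Degenerate inputs: empty region lists, empty libraries and empty
  summaries are returned as empty objects, not errors; all-zero count
  vectors, negative counts and empty vectors are errors for the Gini
  utility; a guide whose 30-nt context is clipped at a chromosome end gets
  an `NA` on-target score with a warning.
* The Gini index is computed via the sorted closed form, equivalent to the
  double-sum definition \(G = \sum_{ij} |x_i - x_j| / (2 n \sum x)\); the
  test suite checks the equivalence against a literal double-sum oracle. It
  operates on whatever vector it is given — normalisation is the caller's
  choice.
* Random draws (control selection, padding, shuffling) restore the caller's
  RNG state afterwards, so library code does not perturb user sessions.

## Known limitations

Editing is modelled as all-or-nothing within the window (no positional
efficiency weights); the mismatch penalty table is a labelled synthetic
surrogate; on-target scoring is a labelled surrogate interface; off-target
search is exhaustive rather than index-based and thus fixture-scale;
splice annotation covers only the 2-nt donor/acceptor positions; oligomer
template sequences are structural placeholders to be replaced with a
validated cloning design before ordering real pools.
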