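Package: beTiler
Title: Design, Annotate, and Assemble sgRNA Tiling Libraries for Base-Editing Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs single-guide RNA (sgRNA) tiling libraries for
    CRISPR-dependent base-editing screens. Resolves genes or genomic
    regions into target intervals, scans both strands for protospacers
    adjacent to a Cas variant's PAM, enumerates and scores off-target
    sites with a variant-adjusted CFD scheme (allowed PAMs scored as
    100% cutting efficiency, all others 0%), predicts per-editor
    mutational outcomes (splice, nonsense, missense, synonymous,
    noncoding) by retranslating edited codons against transcript
    models, and assembles the final library into order-ready DNA
    oligonucleotides (multiplexed golden-gate or per-guide sensor
    format) with restriction-site filtering and a full audit trail.
    Includes a seeded synthetic genome/annotation generator and
    library quality-control utilities (Gini index, positional
    representation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
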