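Package: dupscope
Title: Per-Gene Duplication Rate Profiling for RNA-Seq Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assesses PCR artifacts in RNA-Seq libraries by relating the
    per-gene read duplication rate to expression level. Counts all and
    duplicate-marked reads per gene from a duplicate-marked BAM and a GTF
    annotation (featureCounts-compatible union-overlap rules, unique and
    multi-mapper tiers), computes RPK/RPKM, fits a logistic model of
    duplication rate versus log10 expression, and reports the baseline
    duplication rate of lowly expressed genes as a library-quality
    indicator. Includes a seedable synthetic-library generator with a
    Poisson PCR-amplification model and a coordinate-based duplicate
    marker for validation, diagnostic plots, and a pipeline-facing
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
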