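Package: azidemut
Title: Mutation Accumulation and Spectrum Analysis for Sodium
    Azide-Mutagenized Selfing Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing chemically induced mutations in
    inbred plant lines propagated by single-seed descent. Implements an
    expectation model for spontaneous mutation accumulation under
    repeated self-fertilization (with a gene-dropping Monte Carlo
    validator), a two-part de novo variant isolation pipeline (callable
    region masking, hard genotype filters, diversity-window and privacy
    filters, genotyping-panel exclusion, structural-variant read-support
    filters), mutation-spectrum summaries (reverse-complement-collapsed
    substitution classes, Ts/Tv, indel length distributions),
    sequence-context statistics around mutated sites (matched-base
    control sampling, per-position relative entropy and G-test
    deviance), genome k-mer composition, coding-consequence
    classification against toy gene models, and deleterious-load
    summaries with Bonferroni-corrected constraint labels. A synthetic
    data generator emulates the statistical structure of a mutagenesis
    experiment (per-line private induced variants with a CC-context
    bias, parent-vs-reference heterogeneity, landrace standing
    variation) and emits ground-truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
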