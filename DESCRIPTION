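Package: httcag
Title: Simulation and Cohort Analysis of HTT CAG Repeat Genotyping
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying constitutional CAG short-tandem-repeat size
    at the huntingtin (HTT) locus in cohort designs. Simulates biallelic
    CAG genotypes under a configurable population allele model with exact
    group sizes and intermediate-allele carrier counts, synthesizes
    capillary-electrophoresis fragment-analysis peak tables with PCR
    stutter, somatic expansion mosaicism, baseline noise and an internal
    size-standard ladder, calls integer germline CAG alleles from peak
    tables via ladder calibration, computes the peak-height-weighted
    somatic expansion index restricted to peaks right of the modal allele,
    classifies alleles into the clinical CAG bands (normal, intermediate,
    incomplete penetrance, full penetrance), and runs the cohort
    statistical layer: per-individual sum of CAG repeats, pooled
    two-sample t tests with Bonferroni threshold adjustment,
    intermediate-allele carrier tallies, and the intermediate-allele
    exclusion re-analysis. A reproducible pipeline orchestrates all
    stages from a single YAML configuration and seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
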