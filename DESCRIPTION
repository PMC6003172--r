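Package: singlestep
Title: Single-Step Genomic Evaluation with SNP Weighting and Major-Gene Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-step genomic best linear unbiased prediction
    (ssGBLUP) of quantitative traits influenced by a major gene, built around
    sparse mixed-model equations with a combined pedigree-genomic relationship
    matrix. Implements pedigree validation, Meuwissen-Luo inbreeding and
    Henderson's sparse A-inverse; genotype quality control and blended
    (weighted) genomic relationship matrices; iterative SNP-variance weighting
    (WssGBLUP) with windowed Max/Sum weight smoothing; evaluation on
    weight-ranked SNP subsets (TABLUP); a multi-trait gene-content model that
    carries a multi-allelic major locus as correlated traits; a daughter yield
    deviation (DYD) validation protocol with the Hotelling-Williams test for
    dependent correlations; and a forward-in-time population simulator
    (overlapping generations, gene dropping with recombination, a six-allele
    major locus) so every stage is testable without proprietary data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
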