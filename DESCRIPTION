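Package: umprofiler
Title: Targeted-Panel Molecular Profiling and Prognostic Stratification for Uveal Melanoma
Version: 0.1.0
Authors@R:
    person("UM", "Profiler Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytical workflow for a 15-gene targeted amplicon panel used to
    profile uveal melanoma: variant-allele-frequency based filter chains with
    clinical-significance classification, detection of bi-allelic imbalance on
    chromosomes 1, 3 and 8 from SNP allele frequencies, four-category mutation
    classification and risk stratification, panel QC and method-concordance
    statistics (Cohen's kappa, Bland-Altman limits of agreement, robust
    FDR-controlled outlier detection), and Kaplan-Meier survival comparison of
    molecular strata. Includes a synthetic-cohort simulator with known ground
    truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    BiocGenerics,
    GenomicRanges,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
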