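Package: menmetab
Title: Metabolomic Subtyping of Meningioma NMR Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for subtyping tumour cohorts from
    one-dimensional proton NMR metabolite profiles. Provides a seeded
    synthetic-cohort generator with planted subtypes, correlated metabolite
    modules and cluster-linked clinical covariates; chemical-shift alignment
    to the lactate reference and non-negative template quantification of toy
    spectra; pseudo-counted quantile normalisation with log2
    median-centering and top-variance feature selection; partitioning
    around medoids with silhouette-based model selection, core-sample
    filtering and nearest-shrunken-centroid or per-metabolite linear-model
    signatures; weighted correlation network analysis (soft-threshold
    adjacency, topological overlap, module eigengenes, kME, module-trait
    statistics, hub extraction and network export); metabolite-set
    enrichment by over-representation and quantitative permutation tests;
    and the cohort statistics layer (Fisher, chi-squared, Welch t, Wilcoxon,
    Kaplan-Meier and log-rank) behind clinical characteristics tables and
    progression-free-survival comparisons. All user-facing functions take
    data frames and return tibbles so stages compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    cluster,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
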