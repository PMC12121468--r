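Package: astromorph
Title: Morphometric Profiling and Morphotype Clustering of 3D Astrocyte Skeletons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the three-dimensional morphology of
    hippocampal astrocytes from SWC skeleton reconstructions and for
    classifying cells into morphotypes. Computes ten per-cell morphological
    features including a 1-micrometre-step 3D Sholl intersection profile,
    reduces the feature table by correlation-matrix PCA with component
    retention by the conjunction of Kaiser's criterion and Horn's parallel
    analysis, clusters cells in retained principal-component space with
    hierarchical, k-means, PAM and self-organizing-map algorithms scored by
    internal validation indices, refines the partition by discriminant
    analysis of principal components (DAPC), and compares genotype and age
    groups with nested ANOVA (animal as the nesting factor), Kruskal-Wallis
    with Dunn's post hoc test, and Pearson chi-square tests on morphotype
    distributions. A stochastic branching-process simulator generates
    skeleton cohorts with known morphotype structure so the whole analysis
    is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    cluster,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
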