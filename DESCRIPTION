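Package: amfsoil
Title: Spatial and Temporal Analysis of Soil Arbuscular Mycorrhizal Fungal
    Communities from Barcoded Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for closed-reference virtual-taxon (VT)
    profiling of arbuscular mycorrhizal fungi (AMF) from barcoded SSU rRNA
    amplicon reads, and for the spatial and temporal community inference
    that follows.  Covers demultiplexing and primer/length filtering of
    reads, parsing of tabular alignment hits with identity/length/e-value
    match criteria and best-hit selection, construction and filtering of
    sample-by-VT community matrices, Bray-Curtis dissimilarity, analytic
    rarefaction, permutational multivariate ANOVA (PERMANOVA) with
    sequential sums of squares, homogeneity of multivariate dispersions,
    Poisson-GLM richness comparisons, logit-scale distance decay of
    community similarity with permutation inference, depth-equalisation
    (thinning) and read-trimming robustness experiments, and a synthetic
    data generator that emulates the statistical structure of a plot-based
    forest soil sampling design so that every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
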