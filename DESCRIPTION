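Package: starveomics
Title: Multi-Omics Quantification, Integration and Network Inference for
    Nutrient-Starvation Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing proteome, metabolome and physiology
    measurements from nutrient-starvation/recovery time-course experiments.
    Implements NSAF spectral-count quantification with abundance and
    replicate-presence filtering, sample-centric metabolite normalization,
    sequential K-nearest-neighbour imputation, Kruskal-Wallis and
    ANOVA/Tukey-HSD testing with Benjamini-Hochberg correction, autoscaled
    PCA/PLS-DA/sparse-PLS latent modelling, relevance-network construction
    from sparse-PLS similarities and pairwise correlations, pairwise lag-1
    Granger causality screening, and functional-bin time profiling with
    biclustering. A synthetic-data generator with a recorded ground truth
    emulates the 6-timepoint by 4-replicate design so every stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    lmtest,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
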