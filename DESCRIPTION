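Package: tractclust
Title: Atlas-Guided Representative-Based Clustering of Tractography Streamlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Clustering of large diffusion-MRI tractography datasets with the
    CATSER algorithm: a two-pass agglomerative hierarchical clustering over a
    Chernoff-bound random sample, using well-spread representative streamlines
    per cluster, Local-Outlier-Factor-adjusted intra- and inter-cluster
    distances, staged outlier elimination, and assignment of the remaining
    streamlines to the resulting prototype clusters. Includes four streamline
    similarity measures (centroid, orientation, Hausdorff and a combined
    partial-matching distance), construction of probabilistic white-matter
    atlases from labeled bundles, atlas-guided distance weighting during
    clustering, greedy spatial matching of clusters to atlas classes, readers
    and writers for TrackVis TRK, MRtrix TCK and a JSON-lines streamline
    format, and synthetic bundle generators for end-to-end evaluation without
    MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    RNifti,
    mclust,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
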