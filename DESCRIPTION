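Package: swarmseg
Title: Lung CT Tumor Segmentation by Swarm-Optimized Intensity Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end pipeline for extracting hyperdense tumors from 2-D lung
    CT slices: speckle suppression with median, adaptive median and average
    filters; contrast enhancement by global or contrast-limited adaptive
    histogram equalization; intensity clustering by k-means, k-median, particle
    swarm optimization (PSO), inertia-weighted PSO and guaranteed-convergence
    PSO maximizing a cluster-validity fitness; brightest-cluster tumor
    extraction with connected-component filtering; filter-quality (speckle
    suppression and mean preservation indices) and pixelwise segmentation
    metrics (sensitivity, specificity, balanced accuracy); plus a seeded
    synthetic lung phantom generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
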