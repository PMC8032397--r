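Package: cemcurate
Title: Curation and Probing of Cellular Electron Microscopy Image Patches
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Standardizes heterogeneous 2D and 3D cellular electron
    microscopy data into 224x224 8-bit patches, removes near-duplicate
    patches by perceptual difference hashing within each source dataset,
    and filters uninformative patches with a Random Forest classifier
    trained on four image-level texture statistics. Also provides
    representation-probing tools for any pluggable image encoder:
    invariance curves from neuron mean firing rates under image
    distortions, feature-map selectivity by Point-Biserial correlation
    against ground-truth masks, and occlusion-based spatial attribution.
    A seeded synthetic-fixture generator emulates EM-like patches and
    duplicate-rich volumes so the whole pipeline is testable without any
    real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    randomForest,
    Rcpp,
    RNifti,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
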