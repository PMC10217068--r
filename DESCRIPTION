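Package: fundushybrid
Title: Hybrid Feature Extraction and ANN Classification of Colour Fundus Images
Version: 0.1.0
Authors@R: person("Fundus", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for multiclass classification of colour
    fundus photographs (cataract, diabetic retinopathy, glaucoma, normal).
    Provides Laplacian-sharpening image enhancement with filter-quality
    metrics, four classical texture/colour descriptor blocks (grey-level
    co-occurrence matrix, fuzzy colour histogram, local binary patterns,
    wavelet sub-band statistics), a pluggable deep-feature backbone with
    PCA reduction, three feature-fusion strategies with exact dimensional
    contracts, a seeded single-hidden-layer neural-network classifier with
    early stopping, one-vs-rest evaluation metrics, a two-stage 80/20
    dataset splitter, nine-fold training-set augmentation, and a synthetic
    fundus-image generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    jpeg
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
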