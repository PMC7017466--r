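Package: earct
Title: Grain-Set Phenotyping of Cereal Ears from X-Ray Computed Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for non-destructive grain-set phenotyping
    of cereal (wheat) ears from X-ray computed tomography: simplified
    parallel-beam filtered back projection with automatic per-projection
    unattenuated-intensity normalization, separation of multiple ears within a
    scan, grain/chaff segmentation with splitting of touching seeds, per-grain
    digital traits (volume, virtual weight, centre of mass, mean attenuation,
    spherical aspect ratio via the minimum covering sphere, surface voxels,
    minimal Feret diameter), a virtual 2 mm sieve, virtual-weight calibration
    against hand-threshed reference weights, and seed-weight profiles along
    the normalized ear axis. Includes a synthetic phantom generator producing
    reconstructed ear volumes with exact per-seed ground truth, so every stage
    is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
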