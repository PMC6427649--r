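Package: seedling3d
Title: Recognition of Transplanted Crop Seedlings from Binocular Stereo
    Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for recognizing transplanted crop
    seedlings (e.g. broccoli) in field stereo images. A binocular pair is
    epipolar-rectified, a dense disparity map is computed by semi-global
    matching (with SAD/SSD block-matching baselines), a colored 3D point
    cloud is reconstructed and cleaned of invalid points, down-sampled to a
    fixed budget with a non-uniform octree grid filter, clustered with a
    Gaussian mixture model fitted by expectation-maximization, the crop
    component is selected by its height advantage over soil and weeds, and
    denoised by k-nearest-neighbor outlier filtering. Evaluation utilities
    compute top-view sensitivity against reference masks and canopy
    envelope-box traits, and a synthetic field-scene generator provides
    fully labeled stereo pairs and point clouds for testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    png,
    jsonlite,
    EBImage,
    stats,
    tools,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
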