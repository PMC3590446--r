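Package: nodtemplate
Title: Deformable Template Matching for Lung Nodule Detection in Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects lung nodules in chest CT-like volumes with deformable
    gray-level templates. Four analytic template shapes (solid sphere,
    hollow sphere, circle, semicircle) with a central-symmetric Gaussian
    gray-level profile are matched against the volume by normalized
    cross-correlation, optimized over position, radius and orientation by
    a genetic algorithm restricted to a segmented candidate search space.
    False positives among the harvested candidates are reduced by a naive
    Bayes classifier over three nodule features (radial nonuniformity,
    mean gray level, 10th-percentile gray level) whose class-conditional
    densities are linear combinations of positive- and negative-weight
    Gaussians fitted by an EM-style procedure. Includes a synthetic
    phantom generator with planted nodules and vessel-like distractors
    for end-to-end evaluation, plus NIfTI/raw volume I/O and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
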