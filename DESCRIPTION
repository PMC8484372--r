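Package: mandivol
Title: Landmark-Driven 3D Mandibular Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions a 3D mandible volume (CBCT-style binary mask or
    grayscale image) into condylar, coronoid, ramus and hemibody segments
    using a landmark-derived cephalometric reference frame and five cutting
    planes, and computes per-segment volumes in cubic millimetres. Includes a
    parametric mandible phantom generator with exact ground truth (including
    unilateral condylar/ramal shrinkage mimicking juvenile idiopathic
    arthritis), a cohort simulator calibrated to published group
    distributions, and the accompanying statistical battery: Shapiro-Wilk
    gating, t tests, chi-square, one-way ANOVA with Tukey or Bonferroni post
    hoc comparisons, percentage differences, intraclass correlation, Dahlberg
    method error and a-priori sample size via the noncentral t distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    igraph
Config/testthat/edition: 3
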