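Package: sbgrad
Title: Dose-Gradient Metrics and Plan-Quality Evaluation for Stereotactic Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing stereotactic radiotherapy (SRS/SBRT) dose
    distributions: exact (sorting-based) cumulative dose-volume histograms and
    the scalar metrics derived from them (Dx, D0.01cc near-maximum dose, mean
    dose, V100% coverage, homogeneity index), Paddick and RTOG conformity
    indices, the traditional gradient index, and two border-gradient metrics
    profiled over percent-of-prescription isodose levels: the steepest border
    gradient (percent Rx dose fall-off per mm, from the shortest 3D distance
    between isodose surfaces) and the volume gradient (isodose volume over
    target volume). Includes readers for DICOM RT Dose and RT Structure Set
    objects and a NIfTI+JSON fixture dialect, contour rasterization, clinical
    goal auditing against fractionation-specific reirradiation constraint
    tables, paired Wilcoxon signed-rank plan comparison, and a synthetic-plan
    generator with closed-form ground truth for every metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
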