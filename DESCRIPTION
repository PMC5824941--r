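Package: prfgaze
Title: Population Receptive Field Coverage and Gaze-Bias Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling population receptive fields (pRFs) from
    bar-sweep retinotopic mapping data with the compressive spatial
    summation (CSS) model, and for downstream visual-field-coverage and
    eye-tracking analyses. Includes a synthetic-data module (bar aperture
    movies, CSS BOLD timecourses, gaze records with controllable group
    biases), grid-plus-refinement voxelwise CSS fitting with variance
    explained and exclusion filters, bootstrapped visual field coverage
    maps with extent and centre-of-mass statistics, jackknife standard
    errors, variance-weighted size-eccentricity regression, a
    two-dimensional two-sample Kolmogorov-Smirnov test, and
    fixation-density / adult-fixation-zone / bias-vector gaze analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
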