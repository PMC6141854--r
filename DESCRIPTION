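Package: lesionload
Title: Atlas-Based Lesion-Load Correlation Analysis for Ischemic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relates acute and chronic ischemic-stroke lesion delineations to
    3-month clinical outcome. Computes atlas-based regional lesion loads from
    co-registered NIfTI-1 lesion masks, derives threshold-based delineations
    (ADC core, Tmax perfusion deficit) and binarized prediction maps, builds
    normalized lesion-frequency maps, correlates regional loads and total
    lesion volume with NIHSS and mRS outcome scores using Pearson correlation
    with percentile-bootstrap confidence intervals and a zero-inclusion
    significance rule, dichotomizes cohorts by revascularization success
    (TICI grade), ranks top-correlating regions, and compares outcome-scale
    correlation profiles with an exact small-sample Wilcoxon signed-rank test.
    Includes a fully ground-truthed synthetic stroke-cohort simulator for
    validating the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
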