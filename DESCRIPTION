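Package: alphamark
Title: Individually Anchored EEG Frequency Bands and the Alpha3/Alpha2
    Biomarker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Resting-state EEG biomarker analysis built on individually
    anchored frequency bands. Detects the theta/alpha transition frequency
    (TF) and the individual alpha frequency (IAF) from electrode-averaged
    Welch spectra, constructs subject-specific delta-gamma bands, computes
    relative band powers and the alpha3/alpha2 upper/low alpha power ratio
    used to stratify mild cognitive impairment cohorts, and estimates
    magnitude-squared coherence over fronto-temporo-parietal electrode
    pairs. Includes a synthetic resting-EEG cohort generator with known
    ground truth (oscillators over a 1/f background, controllable
    inter-channel coupling), EDF and plain-matrix I/O, tertile
    stratification, split-plot ANOVA with Greenhouse-Geisser correction and
    Mauchly's test, age-corrected W scores, and an end-to-end pipeline.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
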