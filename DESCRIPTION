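Package: neglectvr
Title: Classification of Unilateral Visuospatial Neglect from Immersive
    Virtual-Reality Visual Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standalone, explainable classifier for unilateral visuospatial
    neglect built on immersive virtual-reality visual-search gameplay. Eight
    orientation and challenge features (hemispace accuracy and reaction-time
    contrasts, headset and gaze lateral orientation means and set-size slopes)
    are benchmarked against distribution-free normative bounds (Tukey fences
    computed in both the control and the patient cohort, combined by
    conjunction), summed into atypicality, orientation and challenge scores,
    and mapped by a rule-based definition onto neglect, minor-atypicality and
    non-neglect labels with multidimensional category codes. Includes a seeded
    synthetic-cohort simulator emulating the game design, diagnostic-accuracy
    statistics (confusion matrices, Cohen's kappa, exact binomial confidence
    intervals, no-information-rate tests), univariable Poisson risk models,
    and numeric report tables for classifier heatmaps, raycast attention
    histograms and gameplay position maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
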