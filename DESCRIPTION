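Package: liverdss
Title: Difficulty Scoring Systems and Composite Outcomes for Laparoscopic
    Liver Resection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based calculators for four difficulty scoring systems for
    laparoscopic liver resection (Halls, Hasegawa, Kawaguchi and Iwate),
    composite peri-operative outcome measures (operative, postoperative and
    textbook outcome), a calibrated synthetic cohort generator, and the
    statistical machinery to compare the scores: rank concordance, per-class
    logistic odds ratios with separation handling, and random-forest
    permutation variable importance. All user-facing functions take a cohort
    data frame and return tibbles so analyses compose with the pipe.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
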