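Package: equigait
Title: Lame-Limb Discrimination from Inertial Gait Asymmetry at the Trot
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates straight-line trot recordings (vertical displacement of
    head, withers and pelvis plus cannon-bone protraction-retraction angles)
    with controlled single-limb lameness, segments them into time-normalized
    strides, extracts 27 movement-asymmetry features (half-stride asymmetry
    indices, Fourier harmonic energy ratio and phase difference, limb
    retraction asymmetry, stride frequency, range of motion), and classifies
    horses into five groups (sound, right/left fore, right/left hind lame)
    with a class-weighted radial-basis-function support-vector machine tuned
    by grid search and validated by out-of-bag bootstrapping. Includes
    reference confusion-matrix and grade-distribution tables from a clinical
    validation cohort for worked-example statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    kernlab,
    pROC,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    caret,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
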