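Package: shapebias
Title: Cue-Conflict Category Learning: Procedural Stimuli, an Ideal Bayesian
    Observer, and a Compact CNN Harness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying which diagnostic feature a learner relies on
    when several features predict category membership. Procedurally generates
    patch-and-segment category-learning stimuli in which global shape and a
    second feature (patch location and colour, segment colour, mean patch
    size, or global colour) are independently diagnostic, with Both, Conflict,
    Shape and Non-shape test conditions. Provides a sequential
    Dirichlet-multinomial ideal observer over symbolic feature vectors, a
    compact convolutional network harness trained on the rendered images, and
    shared scoring, pattern-classification and reporting utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    png,
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
LinkingTo: Rcpp
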