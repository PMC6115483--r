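Package: murotation
Title: Rotation Recruitment and Relaxation-Time Modelling of Postural Muscle Motor Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulator of a postural skeletal muscle whose motor
    units are recruited in rotation ("shift-like" recruitment) rather than in
    hierarchical size order. Motor-unit pools with power-distributed twitch
    forces are loaded isometrically; units are recruited per shift by weighted
    sampling without replacement until the accumulated twitch force balances
    the load, and per-unit contraction and relaxation times are tallied. The
    package reproduces how the relaxation/contraction time ratio of motor
    units falls with increasing muscle load and with decreasing muscle
    strength, derives energy-crisis threshold loads, and simulates the gradual
    transition of myofascial pain episodes to chronicity as a muscle weakens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
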