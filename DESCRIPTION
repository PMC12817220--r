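Package: ergdissect
Title: Pharmacological Dissection of the Ex Vivo Electroretinogram
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for ex vivo transretinal electroretinogram
    (ERG) flash families recorded under sequential pharmacological blockade.
    Isolates photoreceptor, ON-bipolar and Mueller glial cell (MGC)
    components by intensity-matched trace subtraction, measures
    baseline-referenced component amplitudes, fits Hill-type
    intensity-response functions (Rmax, K, n) per retina, and compares
    genotypes with unequal-variance (Welch) t-tests, Rmax proportionality
    analysis and developmental trajectories. Ships a synthetic ERG waveform
    generator with additive ground-truth components, Hill amplitude
    saturation, condition-dependent component removal, acquisition-chain
    Bessel filtering and seeded noise, so the whole pipeline is testable
    end to end without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
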