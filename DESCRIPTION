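Package: camochoice
Title: Visual Modelling and Choice Analysis for Camouflage Background-Choice Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying background choice and camouflage in benthic fish.
    Implements receptor-noise-limited (RNL) visual modelling of natural substrates
    and fish pattern components (quantum catches, chromatic and achromatic Just
    Noticeable Differences, grey-standard calibration), Weber-contrast-based design
    of experimental grey backgrounds, ethogram scoring of binary background-choice
    trials (settled bouts, first-settled choices), and generalised linear mixed
    models (Gamma log-link and binomial logit with a single random intercept) with
    posterior simulation of predicted medians, compatibility intervals and response
    ratios. A seeded synthetic-data generator emulates the structure of substrate
    photo libraries, colour-changing fish populations and choice experiments so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    png,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
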