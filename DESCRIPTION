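Package: nlpvoice
Title: Synthesis of Nonlinear Vocal Phenomena and Simulation of Listener
    Experiments on Perceived Pitch and Body Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric resynthesis of short nonverbal vocalizations with
    controlled nonlinear vocal phenomena (amplitude modulation, subharmonics
    and deterministic chaos emulated as strong jitter), objective acoustic
    verification (autocorrelation pitch tracking, envelope modulation
    spectra, sideband spacing), deterministic construction of three
    psychoacoustic experiment designs (rating scales, two-alternative forced
    choice with ties, implicit association test), a synthetic listener
    cohort with participant- and prototype-level heterogeneity, and
    multilevel estimation of the effects of each phenomenon on perceived
    pitch, timbre, roughness, height, formidability and aggression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
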