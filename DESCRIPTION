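Package: petsuvr
Title: Validation of Windowed SUVR Against Reference-Tissue DVR for Synaptic Density PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate standardized uptake value ratios (SUVR) computed
    over short scan windows against distribution volume ratios (DVR) from
    simplified reference tissue model 2 (SRTM2), for reference-region PET
    quantification of synaptic density. Provides one-tissue-compartment
    tracer-kinetic simulation with a tri-exponential bolus plasma input,
    frame-schedule sampling and a variance-scaled noise model, SRTM and SRTM2
    basis-function fitting, windowed SUVR computation, a perfusion-confound
    simulation that perturbs group delivery (K1) while holding binding (DVR)
    fixed, group effect-size (Cohen's d) and regression analyses, and a
    synthetic two-group cohort generator with the statistical structure of a
    clinical aging study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
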