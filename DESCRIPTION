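Package: amorphkin
Title: Crystallization Kinetics of Amorphous Pharmaceuticals from Thermal and Diffraction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying the physical stability of amorphous
    (glassy) drugs from differential scanning calorimetry (DSC),
    quasi-isothermal modulated DSC, powder X-ray diffraction (PXRD) and
    dissolution data. Extracts glass-transition and cold-crystallization
    features from thermograms, converts reversing heat capacity to
    residual amorphous fraction and fits the modified Avrami model,
    performs isoconversional Kissinger-Akahira-Sunose (KAS) regression
    with Avrami-Erofeev frequency-factor extraction and ANCOVA comparison
    of annealing conditions, fits split pseudo-Voigt profiles to powder
    patterns for polymorph-ratio quantification, and provides
    classical-nucleation-theory and dissolution-correction utilities.
    Includes a synthetic-data generator emulating the full experimental
    design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    yaml,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
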