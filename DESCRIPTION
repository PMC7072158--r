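Package: pmquant
Title: Plasma-Membrane Localization Metrics and Membrane-Binding Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies plasma-membrane localization of fluorescent fusion
    proteins from confocal images using a morphological annulus procedure
    (threshold, binarize, erode, subtract), yielding percent plasma-membrane
    localization, the PM index (I_PM/I_Cyt), and the dissociation index for
    rapamycin-inducible phosphatase-recruitment assays. Companion in-vitro
    analytics cover liposome co-sedimentation densitometry, charge-matched
    phosphoinositide vesicle design, surface plasmon resonance control
    subtraction, Langmuir isotherm Kd fitting and separate association /
    dissociation kinetic analysis, plus group statistics (means +/- SEM,
    one- and two-way ANOVA). A synthetic-data generator renders ground-truth
    cells, time-lapse stacks, sensorgrams, isotherms and gel lanes so the
    whole pipeline is testable without microscope or Biacore data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    withr,
    jsonlite,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
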