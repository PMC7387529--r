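Package: spheromech
Title: Spheroid Fusion Kinetics and Nanoindentation Viscoelasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of multicellular spheroid biomechanics from
    two complementary experiments. Fits the liquid-drop coalescence law to
    neck-radius trajectories of fusing spheroid pairs to obtain the fusion
    time constant and visco-capillary velocity (effective surface tension over
    viscosity), measures neck and lobe geometry from time-lapse doublet images,
    and inverts spherical nanoindentation load-dwell-retract curves with the
    Hertz model and Ting's viscoelastic solution under power-law rheology to
    obtain the relaxation scale factor and power-law exponent. Derived tissue
    quantities (surface-tension estimate, apparent viscosity, stiffness and
    tension ratios) and group-comparison statistics are included, together
    with synthetic generators for fusion trajectories, doublet image stacks
    and indentation curves so the full pipeline is testable end to end.
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
    nortest,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
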