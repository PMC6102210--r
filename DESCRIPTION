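Package: hepaflux
Title: Hybrid Petri-Net and Flux-Balance Simulation of Hepatocyte Sugar
    and Lipid Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Couples a multi-formalism Petri net (continuous signalling
    and transport kinetics, discrete three-level gene expression) to a
    constraint-based metabolic model of the hepatocyte. Provides a
    quasi-steady-state dynamic flux variability analysis (dFVA) pipeline
    for monosaccharide uptake and triacylglycerol production envelopes,
    and a qualitative Monte Carlo sampler of rule-based regulatory
    trajectories with phase detection, fraction-of-trajectories
    statistics and a regulatory-naive control. Includes a bounded-variable
    simplex solver, a minimal SBML Level 3 + FBC reader/writer, and
    desk-scale synthetic models whose optima and trajectory statistics
    are auditable by hand.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
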