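Package: ffrcell
Title: Coupled Electromechanical Model of a Rat Ventricular Myocyte Under Voltage Clamp
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator of calcium-induced calcium release and
    isometric force generation in a rat ventricular myocyte paced under voltage
    clamp. Couples Markov models of the L-type Ca2+ channel (with Ca-dependent
    inactivation and CaMKII/calcineurin-dependent facilitation) and the
    ryanodine receptor (with a luminal refractoriness sensor) to a
    reaction-diffusion description of the dyadic cleft, calmodulin-based
    frequency decoding by CaMKII and calcineurin in two compartments,
    cAMP-mediated beta-adrenergic modulation, SERCA/phospholamban dynamics, and
    a reduced Rice-type cooperative crossbridge model. Provides steady-state
    pacing runs, per-cycle transient and force metrics, force-frequency
    response tables, EC-coupling gain, and a whole-cell Ca2+ balance audit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, Matrix, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
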