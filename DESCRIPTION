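Package: wavechannel
Title: Buoyancy-Modulated Solute Dispersion in Oscillating Wavy-Walled Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reduced two-time-scale model of solute dispersion in a slender,
    vertical, wavy-walled channel driven by an oscillating pressure difference,
    a canonical configuration for intrathecal drug-delivery modelling. Provides
    closed-form Womersley-type oscillatory base flow, the time-averaged mean
    Lagrangian drift (steady streaming plus Stokes drift), the
    concentration-dependent buoyancy-induced mean flow, and a mapped-grid
    finite-difference integrator for the time-averaged nonlinear
    integro-differential solute transport equation, together with
    streamfunction/vorticity diagnostics, scenario presets, tidy accessors and
    ggplot2 visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
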