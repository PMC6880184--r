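Package: uricosim
Title: PK/PD Modeling and Trial Simulation for Uricosuric Agents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: One-compartment oral pharmacokinetics, a physiological
    serum-urate disposition model with Emax inhibition of renal urate
    reabsorption, the estimation cascade for its parameters (urate
    distribution volume from delta mass balance, fractional reabsorption
    from placebo clearance, Emax/EC50 from interval means), and a
    conservative forward simulator of serum urate under arbitrary dosing
    regimens. Includes non-compartmental analysis, dose-proportionality
    and ratio statistics, and a synthetic single/multiple ascending dose
    study generator so the whole pipeline is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
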