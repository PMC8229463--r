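Package: fexupbpk
Title: Physiologically Based Pharmacokinetic Modelling of Oral Fexuprazan
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A whole-body physiologically based pharmacokinetic (PBPK)
    model for the potassium-competitive acid blocker fexuprazan after
    oral administration in humans. Provides interspecies scaling of
    distribution (allometry, Oie-Tozer steady-state volume, tissue
    partition-coefficient scaling with extraction-ratio correction),
    in vitro to in vivo extrapolation of CYP3A4 enzyme kinetics,
    well-stirred hepatic clearance and oral bioavailability, a
    13-compartment perfusion-limited ODE model integrated with
    fixed-step fourth-order Runge-Kutta, non-compartmental analysis,
    per-subject estimation of the fraction absorbed and additional
    hepatic intrinsic clearance, dose-group pooling with one-way
    ANOVA, and a synthetic clinical-cohort generator for end-to-end
    verification without access to the original trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    knitr
Config/testthat/edition: 3
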