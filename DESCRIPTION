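Package: cagepk
Title: Tissue-Cage Pharmacokinetic and Pharmacodynamic Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models drug disposition in subcutaneously implanted tissue cages.
    Provides cage geometry calculations (diffusible surface area, lumen volume,
    surface-area-to-volume ratio), a two-compartment intravenous-bolus plasma
    model with a forcing-function tissue-cage compartment, log-linear covariate
    and lognormal random-effect machinery, a cross-over trial simulator,
    sequential nonlinear mixed-effects estimation by Laplace-approximated
    marginal likelihood (plasma first, then cage kinetics conditional on
    individual plasma parameters), peak-concentration summaries with pairwise
    estimated-marginal-mean contrasts, and a linear mixed model for
    prostaglandin-E metabolite concentrations with Nakagawa marginal and
    conditional R-squared.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nlme,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
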