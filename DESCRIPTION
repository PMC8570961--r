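Package: meldjm
Title: Joint Modelling of MELD-Na Trajectories and Liver Waitlist Survival
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dynamic survival prediction of liver-transplant
    waitlist candidates with acute-on-chronic liver failure (ACLF). Computes
    MELD and MELD-Na scores and EASL-CLIF organ-failure grades from raw lab
    panels, simulates registry-like waitlist cohorts, fits a joint model that
    couples a mixed-effects model for repeated MELD-Na measurements to a
    proportional-hazards survival model through the current value and slope
    of the latent trajectory, produces updating conditional survival
    predictions, evaluates landmarked time-dependent AUC and censoring
    weighted prediction error against a last-value MELD-Na benchmark, and
    re-runs a counterfactual graft-offer allocation experiment comparing the
    two prioritization rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    ggplot2
Config/testthat/edition: 3
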