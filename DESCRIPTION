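Package: simondmc
Title: Diffusion Model for Conflict Tasks: Simulation, Distributional
    Analysis, and Fitting for Simon-Task Eccentricity Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trial-level simulation of the diffusion model for conflict
    tasks (DMC), in which a constant target-based drift rate is
    superimposed with a transient gamma-pulse of distractor-based
    activation.  Provides distributional analyses of Simon-task data
    (correct-RT distribution quantiles, conditional accuracy functions,
    delta plots), per-participant model fitting by differential evolution
    against a weighted RMSE of CDF and CAF points, a delayed-target-onset
    model variant, a synthetic-data generator that emulates two
    eccentricity-manipulation experimental designs (within-block and
    between-block), and group-level inference (repeated-measures ANOVA,
    paired parameter comparisons, delta-plot shift tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
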