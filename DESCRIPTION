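Package: mapkqb
Title: Bistability and Quasi-Bistability Analysis of the MAPK Signaling
    Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for Bayesian analysis of growth-factor-dependent ERK
    activation in the Raf/MEK/ERK (MAPK) cascade.  Provides a rescaled
    four-state mass-action ODE model with switchable positive and negative
    feedback, adaptive-Metropolis MCMC calibration against normalized
    time-course data and global response coefficients from silencing
    experiments, posterior predictive distributions, a circuit-breaking
    algorithm for closed-form steady-state enumeration and stability
    classification, saddle-node bifurcation sweeps in the input signal,
    and a trajectory classification scheme that distinguishes bistable,
    quasi-bistable, and monostable responses.  A synthetic-data generator
    reproduces the statistical structure of the calibration experiments
    so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
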