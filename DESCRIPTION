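Package: hhmix
Title: Unified Hodgkin-Huxley Gating Models via Deep Nonlinear Mixed Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voltage-clamp protocol simulation, sweep quality-control and
    downsampling, Hodgkin-Huxley gating models whose steady-state and
    time-constant functions are small neural networks individualized by
    random effects and a covariate-augmentation network, two-stage
    nonlinear mixed-effects estimation (conditional MAP followed by a
    first-order conditional estimate of the marginal likelihood), and the
    associated population diagnostics (weighted residuals, empirical Bayes
    estimate pair summaries, visual predictive checks, Q10 temperature
    curves). Includes a synthetic heterogeneous potassium-channel
    population generator with known ground truth so that the whole
    workflow runs without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    deSolve,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
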