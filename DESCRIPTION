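Package: feedbackmod
Title: Product-Feedback Inhibition in Small Metabolic Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic (ODE) models of four feedback-regulated metabolic
    modules - a linear pathway, a bidirectional pathway with a costly
    interconversion, the glutamine-glutamate nitrogen-assimilation cycle,
    and a carbon/nitrogen nutrient-integration module - together with
    their flux-balance-analysis (FBA) optimal-growth oracles. Provides
    Hill-type feedback-inhibition rate laws, stiff integration to steady
    state, direct steady-state solving with Jacobian stability analysis,
    piecewise-analytic and linear-programming FBA, and scenario protocols
    (input-flux sweeps against the FBA envelope, pool-size/growth-rate
    trade-off surfaces, futile-cycle metrics, and nitrogen-upshift
    simulations comparing wild-type and feedback-defective regulation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    boot,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
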