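Package: stptiming
Title: Cerebellar Circuit Model with Short-Term Synaptic Plasticity for
    Sub-Second Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rate-based model of the cerebellar cortical microcircuit in
    which short-term plasticity (STP) of the mossy-fiber to granule-cell
    synapse is the only source of temporal dynamics. Implements a two-pool
    Tsodyks-Markram vesicle model with facilitation and postsynaptic
    desensitization, closed-form steady states and step-response analytics
    (synaptic time constant and transient amplitude), a calibrated
    granule-cell layer with Purkinje-cell readout, climbing-fiber-gated
    supervised learning of granule-to-Purkinje weights with Nesterov
    acceleration and adaptive restart, and the three in-silico protocols
    built on it: pattern-switch transients, delay eyelid conditioning, and
    Bayesian estimation of time intervals with a Weber-fraction fit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
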