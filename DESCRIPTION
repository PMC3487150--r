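Package: actinf
Title: Active Inference Simulators for Discrete Planning and Saccadic Visual Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators for active inference, in which action and perception
    jointly minimize a variational free-energy bound on sensory surprise.
    Implements (i) discrete-state planning-as-inference for partially observed
    Markov decision processes with terminal-state priors: pullback generative
    models, mean-field variational belief updates, free-energy evaluation,
    action selection, exact enumeration and Bellman oracles, and a discretized
    mountain-car demonstration; and (ii) continuous-time generalized predictive
    coding: generalized coordinates of motion, precision-weighted prediction
    errors, gradient-flow filtering, reflex-arc action, Laplace conditional
    precision, and a saccadic visual-search simulator with counterfactual
    salience maps and inhibition of return. Includes seeded fixture generators
    (toy decision processes, synthetic glyph images), plain-text serialization
    of models and traces, and a YAML-configured experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
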