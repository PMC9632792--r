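Package: spinesim
Title: Structural Spine Plasticity in the Olfactory Bulb Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Firing-rate model of the mitral-cell / granule-cell network of
    the olfactory bulb with activity-dependent structural plasticity of the
    reciprocal dendrodendritic synapses. Binary connectivity evolves by
    stochastic, Poisson-rate spine formation and removal driven by the
    steady-state activities of the connected cells, stabilized either by a
    hard top-k competition per granule cell or by competition for a limited
    per-cell resource pool. Includes simplified (Gaussian), naturalistic-style
    and mixture odor stimuli, a synthetic surrogate generator for glomerular
    activation maps, discriminability statistics (per-cell d-prime, optimal
    Fisher discriminant, responsive/divergent classification, change index),
    an activity-independent random-rewiring control model, and the training
    protocols used to study learning, odor-specific adaptation, disinhibition,
    and interference-driven forgetting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    methods,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
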