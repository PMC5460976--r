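Package: painDCM
Title: Dynamic Causal Modelling of Pain-Evoked MEG Responses with Canonical
    Microcircuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and Bayesian inversion of canonical-microcircuit
    neural-mass networks for pain-evoked magnetoencephalographic (MEG)
    responses. Provides generators for roving-oddball stimulus designs with
    attention and laterality factors, an eight-source canonical-microcircuit
    forward model with condition-specific modulation of intrinsic gain and
    extrinsic connectivity, a synthetic lead field and evoked-field
    observation model, enumeration of network-architecture and modulation
    model spaces, variational-Laplace model inversion with a free-energy
    approximation to log model evidence, fixed-effects Bayesian model
    selection and Bayesian model averaging, and a parametric-empirical-Bayes
    group stage with Bayesian model reduction and leave-one-out
    cross-validated prediction of behavioural covariates.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
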