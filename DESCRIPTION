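Package: waderOccu
Title: Joint Multispecies Occupancy Modelling for Wading-Bird Aerial Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Hierarchical Bayesian joint species distribution modelling for
    detection/nondetection data from repeated aerial surveys of wetland
    wading birds. Implements a multispecies occupancy model with imperfect
    detection: a synthetic survey-data generator matched to the Everglades
    Systematic Reconnaissance Flight design, an exact observed-data
    likelihood with the latent occupancy state marginalized out, a
    data-augmented adaptive Metropolis-within-Gibbs sampler with
    community-level priors, Gelman-Rubin convergence diagnostics,
    Savage-Dickey Bayes factors for covariate evidence, Dunn-Smyth
    residual and AUC model checking, and gridded occupancy prediction
    with baseline-versus-alternative scenario comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
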