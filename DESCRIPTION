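Package: wmrsa
Title: Cross-Validated Mahalanobis RSA and Decoding of Working-Memory
    Impulse Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multivariate pattern analysis of impulse-evoked EEG responses
    during working-memory maintenance of orientation stimuli. Implements
    cross-validated squared-Mahalanobis (linear discriminant contrast)
    representational dissimilarity matrices with Ledoit-Wolf shrinkage
    covariance, hypothesis-model regression with residualised and
    split-half controls, trial-wise Mahalanobis orientation decoding with
    a half-cosine basis set, cross-temporal generalisation, permutation
    and cluster-based inference, neural-to-behaviour regressions, and a
    generative simulator of population codes for validating the full
    analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
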