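Package: erpdecode
Title: Single-Trial ERP Decoding with Multivariate Laplace Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoding of semantic category from single-trial event-related
    potentials (ERPs). Implements Bayesian logistic regression with a
    multivariate Laplace prior expressed as a Gaussian scale mixture whose
    auxiliary variables carry a structured (graph-Laplacian) precision
    matrix, fitted by expectation propagation. Includes a synthetic ERP
    generator with known ground-truth discriminative structure, a
    preprocessing chain (band-pass filtering, epoching, amplitude-based
    artifact rejection, feature extraction, leakage-safe standardization),
    stratified cross-validation, sliding-window decoding, unseen-exemplar
    generalization, coupled transfer learning across datasets, exact
    binomial significance testing, and a BrainVision reader.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    pracma,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    jsonlite
Config/testthat/edition: 3
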