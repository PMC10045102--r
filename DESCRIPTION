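Package: fedunroll
Title: Federated Unrolled Model-Based Reconstruction for Accelerated Multi-Coil MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation study of federated learning for accelerated
    multi-coil MRI reconstruction with unrolled model-based networks. Provides
    a heterogeneous multi-site phantom k-space simulator (smooth coil
    sensitivities, Cartesian phase-encode under-sampling with an
    auto-calibration region, complex Gaussian noise), SENSE-type forward and
    adjoint operators with a conjugate-gradient data-consistency solver, a
    compact trainable encoder-decoder regularization network with exact
    reverse-mode gradients, structural-similarity training of the unrolled
    reconstruction, five synchronous full-participation federated optimizers
    (FedAvg, FedAdam, FedYogi, FedAdaGrad, Scaffold), communication-budget
    scheduling at a fixed local-step budget, client-side personalization by
    cross-validated fine-tuning, and SSIM/NRMSE evaluation with study-style
    summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
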