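Package: sgleeg
Title: Sparse Group Lasso Channel and Feature Selection for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapped channel and feature selection for multichannel EEG
    classification. Per-channel feature fusion (band power, time-domain
    statistics, autoregressive coefficients, and discrete-wavelet features)
    yields a grouped design matrix on which a multinomial logistic regression
    model is fitted under a Sparse Group Lasso penalty. The estimator is a
    three-loop scheme: outer coordinate gradient descent on a quadratic model
    of the negative log-likelihood, blockwise coordinate descent over channel
    groups, and a modified inner coordinate descent with closed-form
    thresholding and univariate root finding. Regularization paths, 10-fold
    cross-validated selection of the penalty parameters, holdout evaluation,
    and synthetic EEG/design generators for end-to-end testing are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
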