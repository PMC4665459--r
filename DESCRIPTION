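Package: dtabayes
Title: Bayesian Estimation of Medical Diagnostic Test Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian inference for the accuracy of medical diagnostic tests.
    Conjugate Dirichlet and Beta posteriors give the basic measures for binary
    tests (sensitivity, specificity, predictive values, diagnostic likelihood
    ratios) and paired comparisons of two modalities; ordinal rating data get
    empirical ROC points and a posterior for the area under the ROC curve;
    continuous scores are handled by a Gibbs sampler for the binormal model.
    Specialised estimators correct for verification bias under a
    missing-at-random mechanism, estimate sensitivity and specificity of two
    conditionally independent tests without a gold standard by a latent-class
    Gibbs sampler, and measure the accuracy of combined tests via
    believe-the-positive and believe-the-negative rules, likelihood-ratio
    optimal ROC curves, and logistic-regression risk scores.  Includes
    generators for synthetic data with the exact structure each model assumes,
    bundled textbook datasets, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
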