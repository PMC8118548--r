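Package: dpccn
Title: Trait-Specific Differential Co-Expression Networks via Truncated
    Part-Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-guided differential co-expression network estimation for
    detecting gene-by-gene interactions underlying a quantitative trait.
    Couples a parametric interaction model with a truncated part-correlation
    network metric (dPCCN) so that differential-network edges can be
    classified as type I (product-term) or type II (activation/deactivation)
    interactions via a sign-adjustment rule. Includes elastic-net residual
    adjustment for strong main effects, simulation models with known
    interaction ground truth, ROC/partial-AUC benchmarking against
    sign-adjusted differential correlation networks and exhaustive LASSO
    interaction search, and survival-based validation (Aiken-West moderation
    test, quantile risk classification, Kaplan-Meier, log-rank).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
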