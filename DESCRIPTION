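Package: covnet
Title: Covariate-Adjusted Gene Regulatory Network Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-step construction of sparse gene regulatory networks for a
    target species using the gene-expression profile of a related species as
    auxiliary information. Step one fits per-gene penalized (lasso, ridge,
    elastic-net) regressions of the target expression matrix on the related
    species' expression matrix, with bootstrap augmentation for the
    many-genes-few-samples regime and k-fold cross-validation of the
    regularization strength. Step two estimates a sparse precision matrix
    from the regression residuals by the graphical lasso, selects the penalty
    by the extended Bayesian information criterion, converts the precision
    matrix to partial correlations, and thresholds them at a percentile to
    obtain the network. Includes a synthetic-data generator with known
    ground truth, confusion-matrix evaluation against a gold-standard
    TF-target edge list, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
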