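# The user-facing model fit: both steps in one call, returning a classed
# object with the usual accessor methods.

#' Fit a covariate-adjusted gene regulatory network
#'
#' Runs the full two-step procedure: (1) per-gene penalized regression of
#' the target expression matrix `Y` on the auxiliary species matrix `X`
#' (bootstrap-augmented, penalty cross-validated per gene), and (2)
#' graphical-lasso estimation of the precision matrix of the regression
#' residuals with the penalty chosen by eBIC, followed by conversion to
#' partial correlations and percentile thresholding.
#'
#' When `X` is a named list of candidate auxiliary matrices, the best
#' (species, alpha) combination is first chosen by held-out MSE via
#' [select_best_covariate()] and the network is built from that fit.
#'
#' @param Y Target-species expression matrix (samples x genes).
#' @param X Auxiliary-species expression matrix, or a named list of
#'   candidate matrices.
#' @param alpha Elastic-net mixing parameter; when `X` is a list of
#'   candidates, a vector of alphas to try (if left unspecified, the
#'   candidate set `c(1, 0, 0.5)` — lasso, ridge, elastic net — is used).
#' @param Q CV folds (default 10).
#' @param n_boot Bootstrap-augmented sample count (default 1000).
#' @param sigma2 Bootstrap jitter variance (default 0.001).
#' @param lambda_rule `"min"` or `"one_se"`.
#' @param rho_grid Graphical-lasso penalty grid (default 0.1 to 0.9 by 0.1).
#' @param gamma eBIC gamma (default 0.5).
#' @param percentile Partial-correlation percentile threshold (default 95).
#' @param universe_mode Evaluation universe used by [summary.covnet()] when
#'   a gold standard is attached later (default `"tf_by_target"`).
#' @param seed Integer seed; all randomness (bootstrap, fold assignment)
#'   derives from it.
#' @param n_effective Effective sample size for the eBIC (default: the
#'   number of residual rows).
#' @param glasso_scale `"correlation"` (default) estimates the precision
#'   matrix on the residual correlation matrix, so the fixed rho grid acts
#'   on a scale-free quantity whatever the residual variances are;
#'   `"covariance"` uses the covariance as is. Partial correlations are
#'   invariant to this diagonal rescaling — only the effective penalty
#'   strength changes.
#' @param ... Further arguments passed to [fit_multiresponse()].
#' @return An object of class `covnet` with components `fit`
#'   (`regression_fit`), `precision` (`precision_estimate`), `ebic`
#'   (`ebic_selection`), `network` (`grn_network`), `species`, `mse_table`
#'   (when selection ran), `config` and `call`.
#' @examples
#' d <- generate_dataset(simulation_config(p = 12, n = 10, seed = 3))
#' m <- covnet(d$Y, d$X, alpha = 0.5, n_boot = 120, Q = 5, seed = 3)
#' print(m)
#' @export
covnet <- function(Y, X, alpha = 0.5, Q = 10L, n_boot = 1000L,
                   sigma2 = 0.001, lambda_rule = c("min", "one_se"),
                   rho_grid = seq(0.1, 0.9, by = 0.1), gamma = 0.5,
                   percentile = 95, universe_mode = "tf_by_target",
                   seed = 1L, n_effective = NULL,
                   glasso_scale = c("correlation", "covariance"), ...) {
  lambda_rule <- match.arg(lambda_rule)
  glasso_scale <- match.arg(glasso_scale)
  cl <- match.call()

  mse_table <- NULL; species <- NULL; tie <- FALSE
  if (is.list(X) && !is.matrix(X)) {
    alphas <- if (missing(alpha)) c(1, 0, 0.5) else alpha
    sel <- select_best_covariate(X, Y, alphas = alphas, Q = Q,
                                 n_boot = n_boot, sigma2 = sigma2,
                                 seed = seed, ...)
    fit <- sel$fit; species <- sel$species; alpha <- sel$alpha
    mse_table <- sel$mse_table; tie <- sel$tie
  } else {
    fit <- fit_multiresponse(X, Y,
                             penalty = penalty_spec(alpha = alpha,
                                                    lambda_rule = lambda_rule),
                             Q = Q, n_boot = n_boot, sigma2 = sigma2,
                             seed = seed, ...)
  }

  S <- empirical_covariance(fit$residuals)
  if (glasso_scale == "correlation") {
    if (any(diag(S) <= 0)) {
      stopf("residual variance is zero for some gene; cannot rescale to correlations")
    }
    S <- stats::cov2cor(S)
  }
  if (is.null(n_effective)) n_effective <- nrow(fit$residuals)
  rho_sel <- select_rho(S, n_effective, rho_grid = rho_grid, gamma = gamma)
  r <- partial_correlations(rho_sel$estimate$theta)
  net <- threshold_network(r, percentile = percentile,
                           gene_ids = colnames(Y),
                           rho = rho_sel$selection$chosen_rho)

  structure(
    list(fit = fit, precision = rho_sel$estimate,
         ebic = rho_sel$selection, network = net,
         species = species, mse_table = mse_table, tie = tie,
         config = list(alpha = alpha, Q = Q, n_boot = n_boot,
                       sigma2 = sigma2, lambda_rule = lambda_rule,
                       rho_grid = rho_grid, gamma = gamma,
                       percentile = percentile, glasso_scale = glasso_scale,
                       universe_mode = universe_mode, seed = seed),
         call = cl),
    class = "covnet"
  )
}

#' @export
print.covnet <- function(x, ...) {
  net <- x$network
  n_edges <- sum(net$adjacency) / 2
  cat("Covariate-adjusted gene regulatory network\n")
  if (!is.null(x$species)) {
    cat(sprintf("  auxiliary species : %s (selected by test MSE)\n", x$species))
  }
  cat(sprintf("  genes             : %d\n", length(net$gene_ids)))
  cat(sprintf("  alpha             : %g   test MSE: %.5f\n",
              x$config$alpha, x$fit$mse_test))
  cat(sprintf("  glasso rho (eBIC) : %g\n", x$ebic$chosen_rho))
  cat(sprintf("  |r| threshold     : %.4f (percentile %g)\n",
              net$threshold_value, x$config$percentile))
  cat(sprintf("  edges retained    : %d\n", as.integer(n_edges)))
  invisible(x)
}

#' @export
summary.covnet <- function(object, gold = NULL, ...) {
  out <- list(
    alpha = object$config$alpha,
    mse_test = object$fit$mse_test,
    chosen_rho = object$ebic$chosen_rho,
    ebic_values = object$ebic$ebic_values,
    threshold = object$network$threshold_value,
    n_edges = as.integer(sum(object$network$adjacency) / 2),
    nonzero_coefficients = sum(object$fit$coefficients[-1L, ] != 0),
    lambda_range = range(object$fit$chosen_lambda),
    species = object$species,
    mse_table = object$mse_table
  )
  if (!is.null(gold)) {
    cc <- confusion_vs_gold(object$network, gold,
                            object$config$universe_mode)
    out$confusion <- cc
    out$measures <- diagnostic_measures(cc)
  }
  class(out) <- "summary.covnet"
  out
}

#' @export
print.summary.covnet <- function(x, ...) {
  cat("Two-step network fit\n")
  cat(sprintf("  alpha %g | test MSE %.5f | rho %g | threshold %.4f | %d edges\n",
              x$alpha, x$mse_test, x$chosen_rho, x$threshold, x$n_edges))
  cat(sprintf("  nonzero regression coefficients: %d | lambda in [%.4g, %.4g]\n",
              x$nonzero_coefficients, x$lambda_range[1], x$lambda_range[2]))
  if (!is.null(x$measures)) {
    m <- x$measures; cc <- x$confusion
    cat(sprintf("  vs gold standard (%s): TP %d FP %d FN %d TN %d\n",
                cc$universe_mode, cc$tp, cc$fp, cc$fn, cc$tn))
    cat(sprintf("  precision %.3f | recall %.3f | accuracy %.3f | specificity %.3f\n",
                m$precision, m$recall, m$accuracy, m$specificity))
  }
  invisible(x)
}

#' @export
coef.covnet <- function(object, ...) object$fit$coefficients

#' @export
residuals.covnet <- function(object, ...) object$fit$residuals

#' Predict target expression from new auxiliary data
#'
#' Applies the fitted regression to new auxiliary-species samples on the
#' standardized scale of the training data and returns predictions on the
#' original scale of `Y`.
#'
#' @param object A fitted `covnet` model.
#' @param newdata Auxiliary expression matrix (samples x covariate genes, in
#'   the training column order).
#' @param ... Unused.
#' @return Matrix of predicted expression values (samples x target genes).
#' @export
predict.covnet <- function(object, newdata, ...) {
  fit <- object$fit
  x <- sweep(sweep(as.matrix(newdata), 2L, fit$x_center), 2L, fit$x_scale, "/")
  pred_std <- cbind(1, x) %*% fit$coefficients
  sweep(sweep(pred_std, 2L, fit$y_scale, "*"), 2L, fit$y_center, "+")
}

#' Plot an eBIC profile and the partial-correlation threshold
#'
#' Two base-graphics panels: the eBIC value across the rho grid (chosen rho
#' marked) and a histogram of the nonzero absolute partial correlations with
#' the retained-edge threshold.
#'
#' @param x A fitted `covnet` model.
#' @param ... Unused.
#' @export
plot.covnet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  sel <- x$ebic
  plot(sel$rho_grid, sel$ebic_values, type = "b", xlab = expression(rho),
       ylab = "eBIC", main = "Penalty selection")
  graphics::abline(v = sel$chosen_rho, lty = 2)
  vals <- abs(x$network$weights[upper.tri(x$network$weights)])
  vals <- vals[vals != 0]
  if (length(vals) > 0L) {
    graphics::hist(vals, breaks = 30, xlab = "|partial correlation|",
                   main = "Thresholding")
    graphics::abline(v = x$network$threshold_value, lty = 2)
  }
  invisible(x)
}
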