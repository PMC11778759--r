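# Step 1: covariate adjustment. Standardize, bootstrap-augment, fit
# per-gene penalized regressions of the target expression on the auxiliary
# species, select the regularization by k-fold CV, and return the residual
# matrix that feeds the graphical-lasso step.

#' Penalty specification for the regression step
#'
#' @param alpha Elastic-net mixing parameter in [0, 1]: 1 = lasso, 0 = ridge,
#'   intermediate values mix the two penalties
#'   `(1 - alpha)/2 * ||b||_2^2 + alpha * ||b||_1`.
#' @param lambda_grid `"auto"` (100 log-spaced values from lambda_max down to
#'   `1e-3 * lambda_max`) or a strictly descending vector of positive values.
#' @param lambda_rule `"min"` (lambda at minimum CV error; the default) or
#'   `"one_se"` (largest lambda within one standard error of the minimum).
#' @return A `penalty_spec` list.
#' @export
penalty_spec <- function(alpha = 1, lambda_grid = "auto",
                         lambda_rule = c("min", "one_se")) {
  lambda_rule <- match.arg(lambda_rule)
  if (!is_number(alpha) || alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  if (!identical(lambda_grid, "auto")) {
    if (!is.numeric(lambda_grid) || length(lambda_grid) == 0L ||
        any(lambda_grid < 0) || any(diff(lambda_grid) >= 0)) {
      stopf("lambda_grid must be 'auto' or a strictly descending vector >= 0")
    }
  }
  structure(list(alpha = alpha, lambda_grid = lambda_grid,
                 lambda_rule = lambda_rule),
            class = "penalty_spec")
}

#' Center and scale the columns of a matrix
#'
#' Each column is centered to mean 0 and scaled to sample standard deviation
#' 1 (denominator n - 1). Centers and scales are returned for the inverse
#' transform.
#'
#' @param m Numeric matrix; every column must have nonzero variance.
#' @return A list with `values`, `centers`, `scales`.
#' @export
standardize <- function(m) {
  m <- as.matrix(m)
  centers <- colMeans(m)
  scales <- apply(m, 2L, sd)
  zero <- which(scales == 0 | !is.finite(scales))
  if (length(zero) > 0L) {
    nm <- if (is.null(colnames(m))) as.character(zero) else colnames(m)[zero]
    stopf("zero-variance column(s): %s", paste(nm, collapse = ", "))
  }
  vals <- sweep(sweep(m, 2L, centers), 2L, scales, "/")
  list(values = vals, centers = centers, scales = scales)
}

#' Bootstrap augmentation with Gaussian jitter
#'
#' Resamples rows of (X, Y) jointly with replacement up to `n_boot` rows and
#' adds independent N(0, sigma2 I) jitter to each resampled row of each
#' matrix, so that repeated copies of a source row do not coincide exactly.
#' This is the device used to lift an n << p dataset (a handful of time
#' points) to a workable sample size before cross-validation.
#'
#' @param X,Y Row-aligned matrices (same samples).
#' @param n_boot Number of augmented rows (default 1000).
#' @param sigma2 Jitter variance (default 0.001).
#' @param seed Integer seed.
#' @param sigma2_x,sigma2_y Per-matrix overrides of `sigma2`.
#' @return An `augmented_data` list: `X_aug`, `Y_aug`, `n_boot`, `sigma2`,
#'   `seed`, `source_rows` (the shared bootstrap indices).
#' @export
bootstrap_augment <- function(X, Y, n_boot = 1000L, sigma2 = 0.001, seed = 1L,
                              sigma2_x = sigma2, sigma2_y = sigma2) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("X and Y must have the same number of rows")
  if (!is_count(n_boot, 1L)) stopf("n_boot must be a positive integer")
  if (sigma2_x < 0 || sigma2_y < 0) stopf("sigma2 must be >= 0")
  set.seed(seed)
  idx <- sample.int(nrow(X), n_boot, replace = TRUE)
  x_aug <- X[idx, , drop = FALSE] +
    matrix(rnorm(n_boot * ncol(X), sd = sqrt(sigma2_x)), n_boot)
  y_aug <- Y[idx, , drop = FALSE] +
    matrix(rnorm(n_boot * ncol(Y), sd = sqrt(sigma2_y)), n_boot)
  rownames(x_aug) <- rownames(y_aug) <- sprintf("b%04d", seq_len(n_boot))
  structure(
    list(X_aug = x_aug, Y_aug = y_aug, n_boot = as.integer(n_boot),
         sigma2 = sigma2, sigma2_x = sigma2_x, sigma2_y = sigma2_y,
         seed = as.integer(seed), source_rows = idx),
    class = "augmented_data"
  )
}

# Pathwise lambda grid: 100 log-spaced values from lambda_max (smallest
# penalty zeroing every lasso coefficient) down to 1e-3 * lambda_max. For
# small alpha the lasso lambda_max is rescaled by max(alpha, 0.001) so the
# ridge path covers a comparable effective range.
auto_lambda_grid <- function(X, y, alpha, nlambda = 100L,
                             lambda_min_ratio = 1e-3) {
  yc <- y - mean(y)
  lam_max <- max(abs(crossprod(X, yc))) / (nrow(X) * max(alpha, 0.001))
  if (lam_max <= 0) lam_max <- 1
  exp(seq(log(lam_max), log(lam_max * lambda_min_ratio), length.out = nlambda))
}

#' Elastic-net coefficient path by cyclic coordinate descent
#'
#' Solves, for each lambda on a descending grid with warm starts,
#' `argmin (1/(2n)) ||y - b0 - X b||^2 + lambda ((1-alpha)/2 ||b||_2^2 +
#' alpha ||b||_1)` with the intercept `b0` unpenalized. The coordinate update
#' is the soft-thresholding rule `S(z, lambda*alpha) / (x_j'x_j/n +
#' lambda*(1-alpha))`.
#'
#' @param X Design matrix WITHOUT an intercept column (the intercept is
#'   handled internally).
#' @param y Response vector.
#' @param alpha Elastic-net mixing parameter in [0, 1].
#' @param lambdas Descending vector of penalty values.
#' @param tol Convergence tolerance on the largest coefficient change per
#'   sweep (default 1e-7).
#' @param max_iter Maximum sweeps per lambda (default 1e5).
#' @return A `(q + 1) x nlambda` matrix of coefficients; row 1 is the
#'   intercept. Attribute `"iterations"` gives sweeps used per lambda.
#' @export
enet_path <- function(X, y, alpha, lambdas, tol = 1e-7, max_iter = 1e5L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) stopf("non-finite entries in input")
  if (any(diff(lambdas) > 0)) stopf("lambdas must be descending")
  fit <- .enet_path_cpp(X, as.numeric(y), as.numeric(lambdas), alpha,
                        tol, as.integer(max_iter))
  iters <- fit[nrow(fit), ]
  if (any(iters >= max_iter)) {
    stopf("coordinate descent did not converge within %d sweeps (lambda index %d)",
          max_iter, which(iters >= max_iter)[1L])
  }
  coefs <- fit[-nrow(fit), , drop = FALSE]
  rownames(coefs) <- c("(Intercept)",
                       colnames(X) %||% paste0("x", seq_len(ncol(X))))
  attr(coefs, "iterations") <- iters
  coefs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit one penalized response at a fixed penalty
#'
#' Single-response elastic net at one lambda; the design matrix carries an
#' explicit intercept column (all ones, unpenalized), matching the layout in
#' which the coefficient matrix stores intercepts in its first row.
#'
#' @param X Design matrix whose FIRST column is the intercept (all ones);
#'   remaining columns should be standardized.
#' @param y Response vector.
#' @param alpha Elastic-net mixing parameter.
#' @param lam Penalty value (>= 0).
#' @param tol,max_iter Convergence controls (see [enet_path()]).
#' @return Named coefficient vector of length `ncol(X)` (intercept first).
#' @export
fit_penalized_response <- function(X, y, alpha, lam, tol = 1e-7,
                                   max_iter = 1e5L) {
  X <- as.matrix(X)
  if (!all(X[, 1L] == 1)) stopf("first column of X must be the intercept (all ones)")
  if (!is_number(lam) || lam < 0) stopf("lam must be a single value >= 0")
  coefs <- enet_path(X[, -1L, drop = FALSE], y, alpha, lam,
                     tol = tol, max_iter = max_iter)
  b <- coefs[, 1L]
  names(b) <- c("(Intercept)",
                colnames(X)[-1L] %||% paste0("x", seq_len(ncol(X) - 1L)))
  b
}

#' Deterministic fold assignment for k-fold cross-validation
#'
#' @param n Number of rows.
#' @param Q Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of length `n` with fold labels 1..Q, near-equal
#'   block sizes.
#' @export
cv_folds <- function(n, Q, seed) {
  if (!is_count(Q, 2L)) stopf("Q must be an integer >= 2")
  if (n < Q) stopf("need at least Q rows (n = %d, Q = %d)", n, Q)
  set.seed(seed)
  sample(rep_len(seq_len(Q), n))
}

# Core CV loop over a precomputed fold assignment (labels 1..Q per row; the
# labels may group rows, e.g. all bootstrap copies of one source sample).
# For each fold, fit the whole lambda path on the training rows and score
# per-observation RSS on the held-out block; average fold MSEs and record
# their standard error.
cv_core <- function(X, y, alpha, folds, lambda_grid, tol, max_iter) {
  Q <- max(folds)
  nlam <- length(lambda_grid)
  fold_mse <- matrix(NA_real_, Q, nlam)
  for (q in seq_len(Q)) {
    tr <- folds != q
    coefs <- enet_path(X[tr, , drop = FALSE], y[tr], alpha, lambda_grid,
                       tol = tol, max_iter = max_iter)
    pred <- cbind(1, X[!tr, , drop = FALSE]) %*% coefs
    fold_mse[q, ] <- colMeans((y[!tr] - pred)^2)
  }
  mse <- colMeans(fold_mse)
  se <- apply(fold_mse, 2L, sd) / sqrt(Q)
  i_min <- which.min(mse)
  within <- which(mse <= mse[i_min] + se[i_min])
  i_1se <- within[which.max(lambda_grid[within])]
  structure(
    list(lambda_grid = lambda_grid, mse_per_lambda = mse, se_per_lambda = se,
         lambda_min = lambda_grid[i_min], lambda_1se = lambda_grid[i_1se],
         folds = Q, fold_mse = fold_mse),
    class = "cv_result"
  )
}

#' Cross-validate the penalty for one response
#'
#' Rows are randomly partitioned into Q near-equal blocks (deterministic
#' under `seed`); for each lambda the model is fitted on Q - 1 blocks and
#' the residual sum of squares on the held-out block, normalized per
#' observation, is averaged over blocks. `lambda_min` minimizes the CV MSE;
#' `lambda_1se` is the largest lambda whose MSE is within one standard error
#' of that minimum (the "one-standard-error rule").
#'
#' @param X Design matrix without intercept column.
#' @param y Response vector.
#' @param alpha Elastic-net mixing parameter.
#' @param Q Number of folds (>= 2; default 10).
#' @param lambda_grid `"auto"` or a descending vector of penalties.
#' @param seed Integer seed for the fold assignment.
#' @param tol,max_iter Convergence controls.
#' @return A `cv_result` list: `lambda_grid`, `mse_per_lambda`,
#'   `se_per_lambda`, `lambda_min`, `lambda_1se`, `folds`, `fold_mse`.
#' @export
cross_validate_lambda <- function(X, y, alpha, Q = 10L, lambda_grid = "auto",
                                  seed = 1L, tol = 1e-7, max_iter = 1e5L) {
  X <- as.matrix(X)
  if (identical(lambda_grid, "auto")) {
    lambda_grid <- auto_lambda_grid(X, y, alpha)
  }
  if (length(lambda_grid) == 0L) stopf("lambda grid is empty")
  folds <- cv_folds(nrow(X), Q, seed)
  cv_core(X, y, alpha, folds, lambda_grid, tol, max_iter)
}

#' Fit the full multi-response penalized regression
#'
#' The whole of step 1 for one (target, auxiliary) species pair:
#' standardizes both matrices, bootstrap-augments once, cross-validates the
#' penalty per response (one shared fold assignment), refits each response
#' at its selected lambda on the full augmented data, and assembles the
#' coefficient matrix and the residual matrix
#' `E = Y_aug - cbind(1, X_aug) %*% B` over all augmented rows.
#'
#' @param X Auxiliary-species expression matrix (n x q, samples by genes).
#' @param Y Target-species expression matrix (n x p), row-aligned with `X`.
#' @param penalty A [penalty_spec()].
#' @param Q CV folds (default 10).
#' @param n_boot Augmented sample count (default 1000).
#' @param sigma2 Bootstrap jitter variance (default 0.001).
#' @param seed Integer seed (split into bootstrap/fold substreams).
#' @param cv_mode `"grouped"` (default) assigns CV folds at the level of the
#'   original samples, so all bootstrap copies of one sample stay in the
#'   same fold; `"augmented"` folds the augmented rows directly. The grouped
#'   assignment keeps held-out blocks genuinely unseen — with `"augmented"`,
#'   jittered copies of a sample occur on both sides of every split and the
#'   CV error collapses toward the jitter variance, which drives lambda to
#'   near-interpolation and strips the residuals of the very conditional
#'   structure step 2 estimates.
#' @param residuals_on `"augmented"` (default: residuals over all augmented
#'   rows, dimension n_boot x p) or `"original"` (residuals on the
#'   standardized original samples).
#' @param shared_lambda If `TRUE`, average CV curves across responses on a
#'   common grid and use one lambda for all responses (faster; default
#'   `FALSE`, per-response lambda).
#' @param tol,max_iter Convergence controls.
#' @return A `regression_fit` list: `coefficients` ((q+1) x p, intercepts in
#'   row 1), `chosen_lambda` (length p), `alpha`, `residuals`, `mse_test`
#'   (cross-validated per-observation squared prediction error at the chosen
#'   lambda, averaged over responses), `lambda_rule`, `n_aug`, `seed`, and
#'   the standardization records.
#' @export
fit_multiresponse <- function(X, Y, penalty = penalty_spec(), Q = 10L,
                              n_boot = 1000L, sigma2 = 0.001, seed = 1L,
                              cv_mode = c("grouped", "augmented"),
                              residuals_on = c("augmented", "original"),
                              shared_lambda = FALSE,
                              tol = 1e-7, max_iter = 1e5L) {
  residuals_on <- match.arg(residuals_on)
  cv_mode <- match.arg(cv_mode)
  stopifnot(inherits(penalty, "penalty_spec"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("X and Y must be row-aligned (same samples)")
  p <- ncol(Y)

  sx <- standardize(X)
  sy <- standardize(Y)
  aug <- bootstrap_augment(sx$values, sy$values, n_boot = n_boot,
                           sigma2 = sigma2, seed = sub_seed(seed, "bootstrap"))
  x_aug <- aug$X_aug; y_aug <- aug$Y_aug

  folds <- if (cv_mode == "grouped") {
    src_fold <- cv_folds(nrow(X), Q, sub_seed(seed, "folds"))
    src_fold[aug$source_rows]
  } else {
    cv_folds(n_boot, Q, sub_seed(seed, "folds"))
  }
  alpha <- penalty$alpha

  grids <- vector("list", p)
  for (j in seq_len(p)) {
    grids[[j]] <- if (identical(penalty$lambda_grid, "auto")) {
      auto_lambda_grid(x_aug, y_aug[, j], alpha)
    } else penalty$lambda_grid
  }

  chosen <- numeric(p)
  mse_at_chosen <- numeric(p)
  bhat <- matrix(0, ncol(X) + 1L, p,
                 dimnames = list(c("(Intercept)",
                                   colnames(X) %||% paste0("x", seq_len(ncol(X)))),
                                 colnames(Y) %||% paste0("y", seq_len(p))))
  pick_idx <- function(cv) {
    lam <- if (penalty$lambda_rule == "min") cv$lambda_min else cv$lambda_1se
    which(cv$lambda_grid == lam)[1L]
  }
  if (shared_lambda) {
    grid <- grids[[which.max(vapply(grids, max, 0))]]
    total_mse <- 0
    curves <- matrix(NA_real_, p, length(grid))
    for (j in seq_len(p)) {
      cv <- cv_core(x_aug, y_aug[, j], alpha, folds, grid, tol, max_iter)
      curves[j, ] <- cv$mse_per_lambda
      total_mse <- total_mse + cv$mse_per_lambda
    }
    i_lam <- which.min(total_mse)
    chosen[] <- grid[i_lam]
    mse_at_chosen <- curves[, i_lam]
    for (j in seq_len(p)) {
      bhat[, j] <- enet_path(x_aug, y_aug[, j], alpha, chosen[j],
                             tol, max_iter)[, 1L]
    }
  } else {
    for (j in seq_len(p)) {
      cv <- tryCatch(
        cv_core(x_aug, y_aug[, j], alpha, folds, grids[[j]], tol, max_iter),
        error = function(e) stopf("response %d: %s", j, conditionMessage(e))
      )
      i_lam <- pick_idx(cv)
      chosen[j] <- cv$lambda_grid[i_lam]
      mse_at_chosen[j] <- cv$mse_per_lambda[i_lam]
      bhat[, j] <- enet_path(x_aug, y_aug[, j], alpha, chosen[j],
                             tol, max_iter)[, 1L]
    }
  }
  mse_test <- mean(mse_at_chosen)

  resid_mat <- if (residuals_on == "augmented") {
    y_aug - cbind(1, x_aug) %*% bhat
  } else {
    sy$values - cbind(1, sx$values) %*% bhat
  }

  structure(
    list(coefficients = bhat, chosen_lambda = chosen, alpha = alpha,
         residuals = resid_mat, mse_test = mse_test,
         mse_per_response = mse_at_chosen,
         lambda_rule = penalty$lambda_rule, residuals_on = residuals_on,
         cv_mode = cv_mode, n_aug = aug$n_boot, sigma2 = sigma2, Q = Q,
         seed = as.integer(seed),
         x_center = sx$centers, x_scale = sx$scales,
         y_center = sy$centers, y_scale = sy$scales),
    class = "regression_fit"
  )
}

#' Select the minimum-MSE row of a (species, alpha) MSE table
#'
#' The selection rule used to pick the best auxiliary species and penalty:
#' strict argmin of the test MSE; ties are broken first by the order of
#' `alpha_order` (as listed by the caller), then by lexicographic species
#' name, and a tie is flagged in the result.
#'
#' @param mse_table A data.frame with columns `species`, `alpha`, `mse`.
#' @param alpha_order Alpha values in caller preference order (default: order
#'   of first appearance in the table).
#' @return A list with `species`, `alpha`, `mse`, `tie` (logical).
#' @export
select_best_from_table <- function(mse_table, alpha_order = unique(mse_table$alpha)) {
  stopifnot(all(c("species", "alpha", "mse") %in% names(mse_table)))
  best <- min(mse_table$mse)
  cand <- mse_table[mse_table$mse == best, , drop = FALSE]
  ord <- order(match(cand$alpha, alpha_order), cand$species)
  pick <- cand[ord[1L], ]
  list(species = pick$species, alpha = pick$alpha, mse = pick$mse,
       tie = nrow(cand) > 1L)
}

#' Pick the best auxiliary species and penalty by test MSE
#'
#' Fits [fit_multiresponse()] for every (candidate species, alpha)
#' combination and returns the pair with the smallest held-out MSE, along
#' with the full MSE table. Candidate gene sets must match the target's gene
#' identifiers exactly (columns are reordered to the target's order);
#' positional matching is refused.
#'
#' @param candidates Named list of auxiliary expression matrices.
#' @param Y Target expression matrix.
#' @param alphas Penalty mixing values to try, in preference order for tie
#'   breaking (default `c(1, 0, 0.5)`: lasso, ridge, elastic net).
#' @param Q,n_boot,sigma2,seed,... Passed to [fit_multiresponse()].
#' @return A list with `species`, `alpha`, `fit` (the winning
#'   `regression_fit`), `mse_table` (data.frame of all combinations) and
#'   `tie`.
#' @export
select_best_covariate <- function(candidates, Y, alphas = c(1, 0, 0.5),
                                  Q = 10L, n_boot = 1000L, sigma2 = 0.001,
                                  seed = 1L, ...) {
  if (!is.list(candidates) || length(candidates) == 0L) {
    stopf("candidates must be a non-empty named list of matrices")
  }
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    stopf("every candidate needs a species name")
  }
  if (length(alphas) == 0L) stopf("alphas must be nonempty")
  y_genes <- colnames(Y)
  for (nm in names(candidates)) {
    cg <- colnames(candidates[[nm]])
    if (!is.null(y_genes) && !is.null(cg)) {
      if (!setequal(cg, y_genes)) {
        stopf("candidate '%s' gene set does not match the target's", nm)
      }
      candidates[[nm]] <- candidates[[nm]][, y_genes, drop = FALSE]
    } else if (ncol(candidates[[nm]]) != ncol(Y)) {
      stopf("candidate '%s' has %d genes, target has %d (ids unavailable)",
            nm, ncol(candidates[[nm]]), ncol(Y))
    }
  }
  rows <- list(); fits <- list()
  for (nm in names(candidates)) {
    for (a in alphas) {
      fit <- fit_multiresponse(candidates[[nm]], Y,
                               penalty = penalty_spec(alpha = a),
                               Q = Q, n_boot = n_boot, sigma2 = sigma2,
                               seed = seed, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        species = nm, alpha = a, mse = fit$mse_test, stringsAsFactors = FALSE)
      fits[[paste(nm, a, sep = "\r")]] <- fit
    }
  }
  mse_table <- do.call(rbind, rows)
  sel <- select_best_from_table(mse_table, alpha_order = alphas)
  list(species = sel$species, alpha = sel$alpha,
       fit = fits[[paste(sel$species, sel$alpha, sep = "\r")]],
       mse_table = mse_table, tie = sel$tie)
}
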