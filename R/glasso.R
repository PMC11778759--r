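# Step 2: sparse precision-matrix estimation on the regression residuals.
# Blockwise-coordinate-descent graphical lasso, eBIC penalty selection over
# a fixed rho grid, partial correlations, and percentile thresholding.

#' Empirical covariance of a residual matrix
#'
#' `S = (1/n) * t(Ec) %*% Ec` with column-centered `Ec` (maximum-likelihood
#' denominator n, matching the Gaussian likelihood the graphical lasso
#' maximizes).
#'
#' @param E Residual matrix (>= 2 rows).
#' @return Symmetric positive-semidefinite p x p matrix.
#' @export
empirical_covariance <- function(E) {
  E <- as.matrix(E)
  if (nrow(E) < 2L) stopf("need at least 2 rows to estimate a covariance")
  ec <- sweep(E, 2L, colMeans(E))
  crossprod(ec) / nrow(E)
}

#' Graphical lasso by blockwise coordinate descent
#'
#' Maximizes `log det(Theta) - tr(S Theta) - rho * ||Theta||_1` by the
#' blockwise algorithm: the working covariance is initialized to
#' `W = S + rho I` (so `w_ii = s_ii + rho` throughout), and each column's
#' off-diagonal block is updated by solving a covariance-form lasso
#' subproblem; sweeps repeat until the mean absolute change of the
#' off-diagonal of W falls below `tol * mean(|off-diagonal of S|)`. The
#' precision matrix is recovered from the final W and block coefficients.
#'
#' @param S Symmetric positive-semidefinite covariance matrix.
#' @param rho Non-negative penalty; larger values give sparser Theta.
#' @param tol Relative convergence tolerance (default 1e-4).
#' @param max_iter Maximum outer sweeps (default 200).
#' @return A `precision_estimate` list: `theta` (precision), `w` (its
#'   covariance dual), `rho`, `converged`, `iterations`.
#' @details With `rho = 0` the problem is unpenalized and `S` must be
#'   nonsingular; the estimate is then `solve(S)`. A diagonal `S` decouples
#'   into one-dimensional problems with `theta_ii = 1/(s_ii + rho)`.
#' @export
graphical_lasso <- function(S, rho, tol = 1e-4, max_iter = 200L) {
  S <- as.matrix(S)
  check_symmetric(S, 1e-8, "covariance matrix")
  if (!is_number(rho) || rho < 0) stopf("rho must be a single value >= 0")
  p <- nrow(S)

  if (rho == 0) {
    theta <- tryCatch(chol2inv(chol(S)), error = function(e) {
      stopf("S is singular at rho = 0; use rho > 0")
    })
    return(new_precision_estimate((theta + t(theta)) / 2, S, rho, TRUE, 0L))
  }

  off <- abs(S[upper.tri(S)])
  w <- S + diag(rho, p)
  # diagonal S (or p == 2 handled by the same loop): decoupled closed form
  if (length(off) == 0L || all(off == 0)) {
    theta <- diag(1 / diag(w), p)
    return(new_precision_estimate(theta, w, rho, TRUE, 0L))
  }

  s_off_mean <- mean(off)
  betas <- matrix(0, p - 1L, p)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    w_old <- w
    for (j in seq_len(p)) {
      idx <- seq_len(p)[-j]
      beta <- .lasso_cov_cpp(w[idx, idx, drop = FALSE], S[idx, j], rho,
                             betas[, j], 1e-9, 10000L)
      betas[, j] <- beta
      w12 <- w[idx, idx, drop = FALSE] %*% beta
      w[idx, j] <- w12
      w[j, idx] <- w12
    }
    delta <- mean(abs(w[upper.tri(w)] - w_old[upper.tri(w_old)]))
    if (delta < tol * s_off_mean) { converged <- TRUE; break }
  }
  if (!converged) {
    stopf("graphical lasso did not converge in %d sweeps", max_iter)
  }

  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- seq_len(p)[-j]
    t_jj <- 1 / (w[j, j] - sum(w[idx, j] * betas[, j]))
    theta[j, j] <- t_jj
    theta[idx, j] <- -betas[, j] * t_jj
  }
  theta <- (theta + t(theta)) / 2
  new_precision_estimate(theta, w, rho, converged, it)
}

new_precision_estimate <- function(theta, w, rho, converged, iterations) {
  structure(
    list(theta = theta, w = w, rho = rho, converged = converged,
         iterations = as.integer(iterations)),
    class = "precision_estimate"
  )
}

#' Extended Bayesian information criterion for a Gaussian graphical model
#'
#' `eBIC = -n * (log det(Theta) - tr(S Theta)) + k * log(n) +
#' 4 * k * gamma * log(p)`, where `k` counts nonzero off-diagonal pairs
#' {i, j} of Theta once (entries with `|theta_ij| > 1e-8`). `gamma = 0`
#' reduces to the ordinary BIC; larger gamma penalizes edges more heavily,
#' which suits p >> n model selection.
#'
#' @param theta Positive-definite precision matrix.
#' @param S Covariance matrix the model was fitted to.
#' @param n Effective sample size.
#' @param gamma eBIC parameter in [0, 1] (default 0.5).
#' @param zero_tol Magnitude below which an entry counts as zero.
#' @return The eBIC value (smaller is better).
#' @export
ebic_score <- function(theta, S, n, gamma = 0.5, zero_tol = 1e-8) {
  ch <- tryCatch(chol(theta), error = function(e) {
    stopf("theta must be positive definite")
  })
  logdet <- 2 * sum(log(diag(ch)))
  k <- sum(abs(theta[upper.tri(theta)]) > zero_tol)
  p <- nrow(theta)
  -n * (logdet - sum(S * theta)) + k * log(n) + 4 * k * gamma * log(p)
}

#' Select the graphical-lasso penalty by eBIC over a grid
#'
#' Runs [graphical_lasso()] for each rho on the grid, scores each estimate
#' with [ebic_score()], and returns the minimizer. Exact eBIC ties are
#' resolved toward the larger (sparser) rho, and the tie is recorded. A rho
#' at which the solver fails is skipped with a warning.
#'
#' @param S Covariance matrix.
#' @param n Effective sample size for the eBIC. When the covariance comes
#'   from bootstrap-augmented residual rows this is conventionally the
#'   augmented row count, but augmented rows are not independent samples, so
#'   the value is an explicit argument rather than something inferred.
#' @param rho_grid Penalty grid (default `seq(0.1, 0.9, by = 0.1)`).
#' @param gamma eBIC gamma (default 0.5).
#' @param tol,max_iter Passed to [graphical_lasso()].
#' @return A list with `selection` (an `ebic_selection`: `rho_grid`,
#'   `ebic_values`, `gamma`, `chosen_rho`, `n_effective`, `tie`) and
#'   `estimate` (the winning `precision_estimate`).
#' @export
select_rho <- function(S, n, rho_grid = seq(0.1, 0.9, by = 0.1), gamma = 0.5,
                       tol = 1e-4, max_iter = 200L) {
  if (length(rho_grid) == 0L) stopf("rho grid is empty")
  fits <- vector("list", length(rho_grid))
  scores <- rep(NA_real_, length(rho_grid))
  for (i in seq_along(rho_grid)) {
    fit <- tryCatch(graphical_lasso(S, rho_grid[i], tol, max_iter),
                    error = function(e) {
                      warnf("rho = %g skipped: %s", rho_grid[i],
                            conditionMessage(e))
                      NULL
                    })
    if (!is.null(fit)) {
      fits[[i]] <- fit
      scores[i] <- ebic_score(fit$theta, S, n, gamma)
    }
  }
  if (all(is.na(scores))) stopf("graphical lasso failed at every rho")
  best <- min(scores, na.rm = TRUE)
  tie_tol <- 1e-9 * max(1, abs(best))
  cand <- which(!is.na(scores) & scores <= best + tie_tol)
  i_best <- cand[which.max(rho_grid[cand])]
  selection <- structure(
    list(rho_grid = rho_grid, ebic_values = scores, gamma = gamma,
         chosen_rho = rho_grid[i_best], n_effective = as.integer(n),
         tie = length(cand) > 1L),
    class = "ebic_selection"
  )
  list(selection = selection, estimate = fits[[i_best]])
}

#' Partial correlations from a precision matrix
#'
#' The Gaussian identity `r_ij = -theta_ij / sqrt(theta_ii * theta_jj)` for
#' i != j, with a zero diagonal. For a positive-definite precision matrix
#' all entries lie in [-1, 1].
#'
#' @param theta Precision matrix with strictly positive diagonal.
#' @return Symmetric matrix of partial correlations, zero diagonal.
#' @export
partial_correlations <- function(theta) {
  theta <- as.matrix(theta)
  d <- diag(theta)
  if (any(d <= 0)) stopf("precision diagonal must be strictly positive")
  r <- -theta / sqrt(outer(d, d))
  diag(r) <- 0
  (r + t(r)) / 2
}

#' Threshold partial correlations into a network
#'
#' The threshold is the given empirical percentile (linear interpolation) of
#' the nonzero absolute off-diagonal partial correlations; pairs at or above
#' it become edges. Exact zeros are excluded from the percentile because the
#' graphical lasso already zeroes most pairs — including them would drive a
#' high percentile of a sparse solution to zero and keep everything. If all
#' off-diagonals are zero the network is empty with threshold 0.
#'
#' @param r Symmetric partial-correlation matrix (zero diagonal).
#' @param percentile Percentile in [0, 100); the default 95 keeps the top 5%
#'   of conditional correlations, and 0 keeps every nonzero pair.
#' @param gene_ids Gene identifiers (defaults to `colnames(r)`).
#' @param rho Penalty recorded in the network metadata (optional).
#' @return A `grn_network` object.
#' @export
threshold_network <- function(r, percentile = 95, gene_ids = colnames(r),
                              rho = NA_real_) {
  if (!is_number(percentile) || percentile < 0 || percentile >= 100) {
    stopf("percentile must be in [0, 100)")
  }
  r <- as.matrix(r)
  check_symmetric(r, 1e-10, "partial-correlation matrix")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(r)))
  vals <- abs(r[upper.tri(r)])
  nz <- vals[vals != 0]
  if (length(nz) == 0L) {
    adj <- matrix(0, nrow(r), ncol(r))
    return(grn_network(r, adj, 0, gene_ids, rho = rho))
  }
  thr <- unname(quantile(nz, percentile / 100, type = 7))
  adj <- (abs(r) >= thr & r != 0) * 1
  diag(adj) <- 0
  grn_network(r, adj, thr, gene_ids, rho = rho)
}
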