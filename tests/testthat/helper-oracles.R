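# Independent oracles used to validate the solvers. These deliberately use
# different algorithms from the package implementation: exhaustive KKT
# enumeration for the elastic net, and ADMM for the graphical lasso.

# Exhaustive sign-pattern solver for the elastic net
#   argmin (1/(2n))||y - b0 - X b||^2
#          + lam * ((1-alpha)/2 ||b||_2^2 + alpha ||b||_1)
# The intercept is concentrated out by centering. For each sign vector
# s in {-1,0,1}^q the stationarity system on the active set is solved and
# the KKT conditions are checked; the unique consistent pattern gives the
# optimum. Feasible only for small q (3^q patterns).
enet_kkt_oracle <- function(X, y, alpha, lam) {
  X <- as.matrix(X)
  n <- nrow(X); q <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  G <- crossprod(Xc) / n
  cvec <- crossprod(Xc, yc) / n
  finish <- function(b) {
    b0 <- ym - sum(xm * b)
    c(`(Intercept)` = b0, b)
  }
  if (lam * alpha == 0) {
    b <- drop(solve(G + diag(lam * (1 - alpha), q), cvec))
    return(finish(b))
  }
  thr <- lam * alpha
  ridge <- lam * (1 - alpha)
  patterns <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), q)))
  for (i in seq_len(nrow(patterns))) {
    s <- patterns[i, ]
    act <- which(s != 0L)
    b <- numeric(q)
    if (length(act) > 0L) {
      A <- G[act, act, drop = FALSE] + diag(ridge, length(act))
      rhs <- cvec[act] - thr * s[act]
      ba <- tryCatch(drop(solve(A, rhs)), error = function(e) NULL)
      if (is.null(ba)) next
      if (any(sign(ba) != s[act])) next
      b[act] <- ba
    }
    grad <- cvec - G %*% b
    inact <- setdiff(seq_len(q), act)
    if (length(inact) > 0L && any(abs(grad[inact]) > thr + 1e-10)) next
    return(finish(b))
  }
  stop("KKT oracle found no consistent sign pattern")
}

# ADMM solver for the graphical lasso objective
#   min_Theta  tr(S Theta) - log det Theta + rho * ||Theta||_1
# (the l1 norm includes the diagonal, whose entries are positive at the
# optimum, matching the W = S + rho I stationarity convention). A different
# algorithm family from the blockwise solver under test.
admm_glasso_oracle <- function(S, rho, tau = 1, max_iter = 5000, tol = 1e-10) {
  p <- nrow(S)
  Z <- diag(p)
  U <- matrix(0, p, p)
  soft <- function(a, t) sign(a) * pmax(abs(a) - t, 0)
  Theta <- diag(p)
  for (i in seq_len(max_iter)) {
    A <- tau * (Z - U) - S
    eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
    d <- (eg$values + sqrt(eg$values^2 + 4 * tau)) / (2 * tau)
    Theta <- eg$vectors %*% (d * t(eg$vectors))
    Z_old <- Z
    Z <- soft(Theta + U, rho / tau)
    U <- U + Theta - Z
    r_primal <- max(abs(Theta - Z))
    r_dual <- max(abs(Z - Z_old))
    if (r_primal < tol && r_dual < tol) break
  }
  (Theta + t(Theta)) / 2
}

# F1 of the off-diagonal support of a precision estimate against a true
# support (two-column matrix of i < j pairs).
f1_of_support <- function(theta, support, zero_tol = 1e-8) {
  p <- nrow(theta)
  est <- abs(theta) > zero_tol & upper.tri(theta)
  truth <- matrix(FALSE, p, p)
  if (nrow(support) > 0L) truth[support] <- TRUE
  tp <- sum(est & truth)
  prec <- if (sum(est) > 0) tp / sum(est) else 0
  rec <- if (sum(truth) > 0) tp / sum(truth) else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# Random symmetric PSD covariance for solver tests.
random_covariance <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * (p + 2)), p + 2, p)
  crossprod(A) / (p + 2)
}
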