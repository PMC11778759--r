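test_that("empirical covariance matches closed forms", {
  E1 <- matrix(rep(c(1, 2, 3), 3), 3, 3, byrow = TRUE)
  expect_equal(empirical_covariance(E1), matrix(0, 3, 3), ignore_attr = TRUE)
  E2 <- rbind(c(1, 0), c(-1, 0))
  expect_equal(empirical_covariance(E2), matrix(c(1, 0, 0, 0), 2, 2),
               ignore_attr = TRUE)
  expect_error(empirical_covariance(matrix(1, 1, 3)), "2 rows")

  set.seed(14)
  sigma0 <- matrix(c(1, 0.5, 0, 0, 0, 0.5, 1, 0.3, 0, 0, 0, 0.3, 1, 0, 0,
                     0, 0, 0, 1, 0.2, 0, 0, 0, 0.2, 1), 5, 5)
  E <- matrix(rnorm(1000 * 5), 1000, 5) %*% chol(sigma0)
  expect_lt(max(abs(empirical_covariance(E) - sigma0)), 0.15)
})

test_that("graphical lasso reproduces the decoupled closed forms", {
  # identity covariance, no penalty: Theta = I
  fit0 <- graphical_lasso(diag(3), rho = 0)
  expect_equal(fit0$theta, diag(3), tolerance = 1e-12)

  # diagonal covariance: theta_ii = 1/(s_ii + rho), off-diagonals zero
  S <- diag(c(0.5, 2, 1.5))
  for (rho in c(0, 0.1, 0.7)) {
    fit <- graphical_lasso(S, rho)
    expect_equal(fit$theta, diag(1 / (diag(S) + rho)), tolerance = 1e-12)
  }
  expect_error(graphical_lasso(matrix(c(1, 1, 1, 1), 2), rho = 0), "singular")
})

test_that("graphical lasso agrees with an ADMM oracle on small problems", {
  # fixed 2x2 instance
  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  ours <- graphical_lasso(S, 0.2, tol = 1e-9, max_iter = 2000)
  oracle <- admm_glasso_oracle(S, 0.2)
  expect_equal(ours$theta, oracle, tolerance = 1e-5)

  # 25 random instances, p in 2..4
  set.seed(40)
  for (i in 1:25) {
    p <- sample(2:4, 1)
    S <- random_covariance(p, seed = 1000 + i)
    rho <- runif(1, 0.05, 0.5)
    ours <- graphical_lasso(S, rho, tol = 1e-9, max_iter = 2000)
    oracle <- admm_glasso_oracle(S, rho)
    expect_equal(ours$theta, oracle, tolerance = 1e-5,
                 label = sprintf("instance %d (p=%d, rho=%.3f)", i, p, rho))
  }
})

test_that("graphical-lasso solutions satisfy the stationarity conditions", {
  set.seed(50)
  for (i in 1:5) {
    S <- random_covariance(10, seed = 600 + i)
    rho <- runif(1, 0.05, 0.3)
    fit <- graphical_lasso(S, rho)
    w <- fit$w; theta <- fit$theta
    # diagonal convention held exactly
    expect_equal(diag(w), diag(S) + rho, tolerance = 1e-12)
    # positive definite and consistent dual
    expect_gt(min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_equal(diag(w %*% theta), rep(1, 10), tolerance = 1e-3)
    # KKT: |s_ij - w_ij| <= rho at zeros; equality with sign at nonzeros
    up <- which(upper.tri(S), arr.ind = TRUE)
    for (k in seq_len(nrow(up))) {
      a <- up[k, 1]; b <- up[k, 2]
      d <- S[a, b] - w[a, b]
      if (abs(theta[a, b]) > 1e-8) {
        expect_equal(d, -rho * sign(theta[a, b]), tolerance = 1e-4)
      } else {
        expect_lte(abs(d), rho + 1e-4)
      }
    }
  }
})

test_that("edge counts are nonincreasing along the rho grid", {
  set.seed(70)
  om <- generate_precision(12, 0.15, seed = 4)
  sigma <- solve(om)
  E <- matrix(rnorm(300 * 12), 300, 12) %*% chol(sigma)
  S <- cov2cor(empirical_covariance(E))
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(rho) {
    th <- graphical_lasso(S, rho)$theta
    sum(abs(th[upper.tri(th)]) > 1e-8)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("partial correlations follow the precision-matrix identity", {
  theta <- matrix(c(2, -1, -1, 2), 2)
  r <- partial_correlations(theta)
  expect_equal(r[1, 2], 0.5)
  expect_equal(diag(r), c(0, 0))

  expect_equal(partial_correlations(diag(c(1, 3, 5))), matrix(0, 3, 3))

  set.seed(9)
  for (i in 1:10) {
    om <- generate_precision(8, 0.4, seed = i)
    r <- partial_correlations(om)
    expect_equal(r, t(r))
    expect_true(all(abs(r) <= 1))
  }
  expect_error(partial_correlations(matrix(c(-1, 0, 0, 1), 2)), "positive")
})

test_that("percentile thresholding retains exactly the top tail", {
  set.seed(33)
  # a 15x15 symmetric r with 100 distinct nonzero values padded by zeros:
  # the percentile is computed over the nonzero entries only
  genes <- sprintf("g%02d", 1:15)
  r <- matrix(0, 15, 15, dimnames = list(genes, genes))
  up <- which(upper.tri(r))
  vals <- seq(0.01, 1, length.out = 100)
  r[up[1:100]] <- vals * sample(c(-1, 1), 100, TRUE)
  r <- r + t(r)
  net <- threshold_network(r, percentile = 95, gene_ids = genes)
  expect_identical(sum(net$adjacency) / 2, 5)
  expect_true(all(abs(net$weights[net$adjacency == 1]) >= net$threshold_value))

  # all zero off-diagonals: empty network, threshold 0
  z <- matrix(0, 4, 4)
  net0 <- threshold_network(z, 95, gene_ids = letters[1:4])
  expect_identical(sum(net0$adjacency), 0)
  expect_identical(net0$threshold_value, 0)

  # percentile 0 keeps every nonzero pair
  net_all <- threshold_network(r, percentile = 0, gene_ids = genes)
  expect_identical(sum(net_all$adjacency) / 2, 100)

  # higher percentile never yields more edges
  net99 <- threshold_network(r, percentile = 99, gene_ids = genes)
  expect_lte(sum(net99$adjacency), sum(net$adjacency))
  expect_error(threshold_network(r, percentile = 100), "percentile")
})
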