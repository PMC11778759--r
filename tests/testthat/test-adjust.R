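test_that("standardize centers and scales with the n-1 denominator", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  s <- standardize(m)
  expect_equal(s$values[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(s$values), c(a = 0, b = 0))
  expect_equal(apply(s$values, 2, sd), c(a = 1, b = 1))
  # idempotence
  s2 <- standardize(s$values)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  # inverse transform
  expect_equal(sweep(sweep(s$values, 2, s$scales, "*"), 2, s$centers, "+"),
               m, ignore_attr = TRUE)
  expect_error(standardize(cbind(a = c(1, 1, 1), b = 1:3)), "a")
})

test_that("bootstrap augmentation resamples jointly and jitters both sides", {
  X <- matrix(rnorm(12), 4, 3)
  Y <- matrix(rnorm(8), 4, 2)
  # zero jitter: every augmented row is an exact copy of its source row
  aug0 <- bootstrap_augment(X, Y, n_boot = 5, sigma2 = 0, seed = 2)
  for (k in seq_len(5)) {
    expect_identical(unname(aug0$X_aug[k, ]), X[aug0$source_rows[k], ])
    expect_identical(unname(aug0$Y_aug[k, ]), Y[aug0$source_rows[k], ])
  }
  # determinism
  expect_identical(bootstrap_augment(X, Y, 50, 0.001, seed = 7),
                   bootstrap_augment(X, Y, 50, 0.001, seed = 7))
  # jitter is mean-zero at the CLT scale over ~1e5 entries
  Xb <- matrix(0, 100, 50)
  Yb <- matrix(0, 100, 50)
  aug <- bootstrap_augment(Xb, Yb, n_boot = 2000, sigma2 = 0.001, seed = 3)
  n_entries <- length(aug$X_aug)
  expect_lt(abs(mean(aug$X_aug)), 4 * sqrt(0.001) / sqrt(n_entries))
  expect_error(bootstrap_augment(X, Y, 5, sigma2 = -1, seed = 1), "sigma2")
  expect_error(bootstrap_augment(X, Y[1:3, ], 5, 0, seed = 1), "same number")
})

test_that("penalized fits agree with closed forms and the KKT oracle", {
  set.seed(42)
  n <- 20; q <- 3
  X <- matrix(rnorm(n * q), n, q)
  X <- scale(X)[, ]  # standardized columns
  y <- drop(X %*% c(1.5, 0, -0.7) + rnorm(n, sd = 0.5))
  Xi <- cbind(1, X)

  # lam = 0: ordinary least squares
  b_ols <- fit_penalized_response(Xi, y, alpha = 1, lam = 0, tol = 1e-10)
  b_lm <- unname(coef(lm(y ~ X)))
  expect_equal(unname(b_ols), b_lm, tolerance = 1e-8)

  # lam >= lambda_max: lasso zeroes all non-intercept coefficients
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / n
  b_zero <- fit_penalized_response(Xi, y, alpha = 1, lam = lam_max * 1.0001)
  expect_identical(unname(b_zero[-1]), c(0, 0, 0))
  expect_equal(unname(b_zero[1]), mean(y))

  # ridge at moderate lambda never gives exact zeros
  b_ridge <- fit_penalized_response(Xi, y, alpha = 0, lam = 0.5)
  expect_true(all(b_ridge[-1] != 0))

  # generic (alpha, lambda): match the exhaustive sign-pattern oracle
  b_cd <- fit_penalized_response(Xi, y, alpha = 1, lam = 0.1, tol = 1e-10)
  b_or <- enet_kkt_oracle(X, y, alpha = 1, lam = 0.1)
  expect_equal(unname(b_cd), unname(b_or), tolerance = 1e-6)
})

test_that("lasso solutions satisfy the KKT conditions", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 30; q <- 5
    X <- scale(matrix(rnorm(n * q), n, q))[, ]
    y <- drop(X %*% rnorm(q) + rnorm(n))
    lam <- runif(1, 0.05, 0.5)
    b <- fit_penalized_response(cbind(1, X), y, alpha = 1, lam = lam,
                                tol = 1e-10)
    r <- y - b[1] - drop(X %*% b[-1])
    g <- drop(crossprod(X, r)) / n
    zero <- b[-1] == 0
    expect_true(all(abs(g[zero]) <= lam + 1e-6))
    if (any(!zero)) {
      expect_equal(unname(g[!zero]), unname(lam * sign(b[-1][!zero])),
                   tolerance = 1e-6)
    }
  }
})

test_that("lasso path shrinks monotonically and matches glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(12)
  n <- 40; q <- 6
  X <- scale(matrix(rnorm(n * q), n, q))[, ]
  y <- drop(X %*% c(2, -1, 0.5, 0, 0, 0) + rnorm(n))
  grid <- exp(seq(log(1), log(0.001), length.out = 40))
  path <- enet_path(X, y, alpha = 1, lambdas = grid)
  l1 <- colSums(abs(path[-1, ]))
  # descending lambda => nondecreasing l1 norm
  expect_true(all(diff(l1) >= -1e-10))

  g <- glmnet::glmnet(X, y, alpha = 1, lambda = grid, standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(unname(path[-1, c(5, 20, 35)]),
               unname(as.matrix(g$beta)[, c(5, 20, 35)]), tolerance = 1e-4)
})

test_that("cross-validation machinery matches a naive fold loop", {
  set.seed(30)
  n <- 30; q <- 4
  X <- scale(matrix(rnorm(n * q), n, q))[, ]
  y <- drop(X %*% c(1, -1, 0, 0.5) + rnorm(n, sd = 0.3))
  grid <- exp(seq(log(0.8), log(0.001), length.out = 25))
  cv <- cross_validate_lambda(X, y, alpha = 1, Q = 5, lambda_grid = grid,
                              seed = 99)

  # naive re-implementation of the fold bookkeeping
  folds <- cv_folds(n, 5, seed = 99)
  fold_mse <- matrix(NA_real_, 5, length(grid))
  for (qq in 1:5) {
    coefs <- enet_path(X[folds != qq, ], y[folds != qq], 1, grid)
    for (l in seq_along(grid)) {
      pred <- coefs[1, l] + X[folds == qq, , drop = FALSE] %*% coefs[-1, l]
      fold_mse[qq, l] <- sum((y[folds == qq] - pred)^2) / sum(folds == qq)
    }
  }
  mse_naive <- colMeans(fold_mse)
  se_naive <- apply(fold_mse, 2, sd) / sqrt(5)
  expect_equal(cv$mse_per_lambda, mse_naive, tolerance = 1e-10)
  expect_equal(cv$se_per_lambda, se_naive, tolerance = 1e-10)
  i_min <- which.min(mse_naive)
  expect_identical(cv$lambda_min, grid[i_min])
  expect_identical(cv$lambda_1se,
                   max(grid[mse_naive <= mse_naive[i_min] + se_naive[i_min]]))
  expect_gte(cv$lambda_1se, cv$lambda_min)

  # noiseless response: smallest lambda wins with near-zero error
  y0 <- drop(X %*% c(1, -1, 0.5, 2))
  cv0 <- cross_validate_lambda(X, y0, alpha = 1, Q = 5, seed = 4)
  expect_identical(cv0$lambda_min, min(cv0$lambda_grid))
  expect_lt(min(cv0$mse_per_lambda), 1e-4)
})

test_that("one-standard-error lambda never falls below lambda_min", {
  set.seed(55)
  for (rep in 1:5) {
    X <- matrix(rnorm(25 * 3), 25, 3)
    y <- rnorm(25)
    cv <- cross_validate_lambda(X, y, alpha = runif(1), Q = 5, seed = rep)
    expect_gte(cv$lambda_1se, cv$lambda_min)
    expect_equal(min(cv$mse_per_lambda),
                 cv$mse_per_lambda[cv$lambda_grid == cv$lambda_min])
  }
})

test_that("multi-response fit is exact in the noiseless case and deterministic", {
  set.seed(61)
  n <- 12; q <- 3; p <- 3
  X <- matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("x", 1:q)))
  B <- matrix(c(1, 0, -1, 0.5, 2, 0, 0, -1.5, 1), q, p)
  Y <- X %*% B
  colnames(Y) <- paste0("g", 1:p)
  grid <- 10^seq(0, -8, by = -0.5)
  fit <- fit_multiresponse(X, Y,
                           penalty = penalty_spec(alpha = 1, lambda_grid = grid),
                           Q = 4, n_boot = 60, sigma2 = 0, seed = 9)
  expect_lt(max(abs(fit$residuals)), 1e-6)

  fit2 <- fit_multiresponse(X, Y,
                            penalty = penalty_spec(alpha = 1, lambda_grid = grid),
                            Q = 4, n_boot = 60, sigma2 = 0, seed = 9)
  expect_identical(fit, fit2)
})

test_that("single-response fit reduces to the scalar solver at the chosen lambda", {
  set.seed(77)
  n <- 15; q <- 4
  X <- matrix(rnorm(n * q), n, q)
  Y <- matrix(X %*% rnorm(q) + rnorm(n, sd = 0.4), n, 1)
  fit <- fit_multiresponse(X, Y, penalty = penalty_spec(alpha = 1),
                           Q = 5, n_boot = 80, sigma2 = 0.001, seed = 31)
  # refit by hand on the same augmented data at the chosen lambda
  sx <- standardize(X); sy <- standardize(Y)
  aug <- bootstrap_augment(sx$values, sy$values, 80, 0.001,
                           seed = covnet:::sub_seed(31, "bootstrap"))
  b <- fit_penalized_response(cbind(1, aug$X_aug), aug$Y_aug[, 1],
                              alpha = 1, lam = fit$chosen_lambda[1])
  expect_equal(unname(fit$coefficients[, 1]), unname(b), tolerance = 1e-10)
})

test_that("lasso adjustment recovers the strong true coefficients", {
  # averaged over 10 seeds, at least 80% of true standardized coefficients
  # of magnitude >= 0.5 are detected as nonzero
  rates <- vapply(1:10, function(s) {
    d <- generate_dataset(simulation_config(p = 20, q = 20, n = 30,
                                            edge_prob = 0.05,
                                            coef_sparsity = 0.1, seed = s))
    fit <- fit_multiresponse(d$X, d$Y, penalty = penalty_spec(alpha = 1),
                             Q = 5, n_boot = 200, seed = s)
    sdx <- apply(d$X, 2, sd); sdy <- apply(d$Y, 2, sd)
    b_std <- sweep(sweep(d$truth$coefficients[-1, ], 1, sdx, "*"), 2, sdy, "/")
    strong <- abs(b_std) >= 0.5
    if (!any(strong)) return(NA_real_)
    mean(fit$coefficients[-1, ][strong] != 0)
  }, 0)
  expect_gte(mean(rates, na.rm = TRUE), 0.8)
})

test_that("ridge keeps every coefficient nonzero on generic data", {
  set.seed(83)
  X <- matrix(rnorm(20 * 8), 20, 8)
  Y <- matrix(rnorm(20 * 3), 20, 3)
  fit <- fit_multiresponse(X, Y, penalty = penalty_spec(alpha = 0),
                           Q = 4, n_boot = 100, seed = 5)
  expect_true(all(fit$coefficients[-1, ] != 0))
})

test_that("the best (species, alpha) pair is chosen by minimum MSE", {
  # printed five-species MSE block: selection must be (ana, elastic net)
  tab <- data.frame(
    species = rep(c("ana", "sim", "per", "pse", "vir"), each = 3),
    alpha = rep(c(1, 0, 0.5), times = 5),
    mse = c(3.29001, 16.12004, 2.99174,
            3.7730, 12.34170, 3.86851,
            4.0201, 15.84112, 3.90572,
            3.78923, 16.55230, 3.73234,
            3.90457, 15.02034, 3.88271))
  sel <- select_best_from_table(tab, alpha_order = c(1, 0, 0.5))
  expect_identical(sel$species, "ana")
  expect_identical(sel$alpha, 0.5)
  expect_equal(sel$mse, 2.99174)
  expect_false(sel$tie)

  # exact ties: first alpha in preference order, then species name; flagged
  tie_tab <- data.frame(species = c("b", "a"), alpha = c(1, 1), mse = c(1, 1))
  sel2 <- select_best_from_table(tie_tab, alpha_order = 1)
  expect_identical(sel2$species, "a")
  expect_true(sel2$tie)
})

test_that("covariate selection fits all pairs and validates gene sets", {
  set.seed(19)
  n <- 10; p <- 6
  genes <- paste0("g", 1:p)
  Y <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, genes))
  X1 <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, genes))
  X2 <- matrix(Y + rnorm(n * p, sd = 0.1), n, p,
               dimnames = list(NULL, rev(genes)))  # informative, shuffled cols
  sel <- select_best_covariate(list(white = X1, related = X2), Y,
                               alphas = c(1, 0.5), Q = 5, n_boot = 80,
                               seed = 3)
  expect_identical(nrow(sel$mse_table), 4L)
  expect_identical(sel$species, "related")
  expect_identical(sel$mse_table$mse[sel$mse_table$species == sel$species &
                                       sel$mse_table$alpha == sel$alpha],
                   sel$fit$mse_test)

  X_bad <- X1[, 1:5]
  colnames(X_bad) <- paste0("h", 1:5)
  expect_error(select_best_covariate(list(bad = X_bad), Y, alphas = 1,
                                     Q = 5, n_boot = 50, seed = 1),
               "gene set")

  one <- select_best_covariate(list(only = X1), Y, alphas = 0.5,
                               Q = 5, n_boot = 50, seed = 1)
  expect_identical(one$species, "only")
  expect_identical(one$alpha, 0.5)
})
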