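# Synthetic-data generator. Emulates the generative assumptions the method
# is built on: Y = [1 X] B + E with E ~ N(0, Omega^-1), a sparse
# positive-definite gene-gene precision matrix Omega, a sparse cross-species
# coefficient matrix B, and the many-genes-few-samples regime (p >> n).

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator. The defaults
#' describe the regime the method targets: a sparse conditional-dependence
#' graph (about 5% of gene pairs), moderate partial-correlation strengths,
#' and a cross-species coefficient matrix with about 10% nonzero entries of
#' unit magnitude — strong enough confounding that the marginal covariance
#' of Y is visibly distorted relative to Omega^-1.
#'
#' @param p Number of genes in the target species (responses).
#' @param n Number of samples (time points); p >> n is the intended regime.
#' @param q Number of covariate genes in the auxiliary species (default `p`;
#'   when `q == p` the two species share gene identifiers, as in matched
#'   cross-species expression panels).
#' @param edge_prob Erdos-Renyi probability of a conditional-dependence edge
#'   between two genes (default 0.05).
#' @param coef_sparsity Fraction of nonzero entries in the (non-intercept
#'   part of the) coefficient matrix B (default 0.1).
#' @param coef_scale Magnitude of nonzero coefficients (default 1; signs are
#'   random).
#' @param noise_partial_corr_range Range of off-diagonal precision magnitudes
#'   before diagonal-dominance scaling (default `c(0.25, 0.75)`).
#' @param seed Integer seed; split into per-component substreams (precision,
#'   coefficients, design, noise) so each piece is individually reproducible.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(p, n, q = p, edge_prob = 0.05,
                              coef_sparsity = 0.1, coef_scale = 1,
                              noise_partial_corr_range = c(0.25, 0.75),
                              seed = 1L) {
  if (!is_count(p, 2L)) stopf("p must be an integer >= 2")
  if (!is_count(n, 2L)) stopf("n must be an integer >= 2")
  if (!is_count(q, 1L)) stopf("q must be a positive integer")
  if (!is_number(edge_prob) || edge_prob < 0 || edge_prob > 1) {
    stopf("edge_prob must be in [0, 1]")
  }
  if (!is_number(coef_sparsity) || coef_sparsity < 0 || coef_sparsity > 1) {
    stopf("coef_sparsity must be in [0, 1]")
  }
  stopifnot(length(noise_partial_corr_range) == 2L,
            noise_partial_corr_range[1] <= noise_partial_corr_range[2])
  structure(
    list(p = as.integer(p), n = as.integer(n), q = as.integer(q),
         edge_prob = edge_prob, coef_sparsity = coef_sparsity,
         coef_scale = coef_scale,
         noise_partial_corr_range = noise_partial_corr_range,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Generate a sparse positive-definite precision matrix
#'
#' Builds a p x p precision matrix with Erdos-Renyi off-diagonal support:
#' each pair {i, j} carries a nonzero entry with probability `edge_prob`,
#' drawn with magnitude uniform in `partial_corr_range` and random sign.
#' Positive definiteness is enforced by diagonal dominance,
#' `diag = 1 + rowSums(|off-diagonal|)`, which guarantees a minimum
#' eigenvalue of at least 1 and — unlike Wishart draws — gives exact,
#' controllable support, the quantity the pipeline is scored on.
#'
#' @param p Number of genes (>= 2).
#' @param edge_prob Edge probability in [0, 1].
#' @param partial_corr_range Length-2 range of off-diagonal magnitudes.
#' @param seed Integer seed (same seed, same matrix).
#' @return A symmetric positive-definite matrix with attribute `"support"`:
#'   a two-column integer matrix of pairs (i < j) with nonzero entries.
#' @export
generate_precision <- function(p, edge_prob, partial_corr_range = c(0.25, 0.75),
                               seed = 1L) {
  if (!is_count(p, 2L)) stopf("p must be an integer >= 2")
  set.seed(seed)
  omega <- matrix(0, p, p)
  up <- which(upper.tri(omega))
  present <- rbinom(length(up), 1L, edge_prob) == 1L
  k <- sum(present)
  if (k > 0L) {
    mag <- runif(k, partial_corr_range[1], partial_corr_range[2])
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    omega[up[present]] <- sgn * mag
  }
  omega <- omega + t(omega)
  diag(omega) <- 1 + rowSums(abs(omega))
  support <- which(upper.tri(omega) & omega != 0, arr.ind = TRUE)
  support <- support[order(support[, 1L], support[, 2L]), , drop = FALSE]
  ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) stopf("internal error: precision matrix not PD")  # cannot occur
  structure(omega, support = unname(support))
}

#' Generate a synthetic cross-species expression dataset
#'
#' Draws X (n x q) i.i.d. standard normal, a sparse coefficient matrix B
#' ((q+1) x p, zero intercept row, a fraction `coef_sparsity` of nonzero
#' entries of magnitude `coef_scale` with random signs), noise E with rows
#' i.i.d. N(0, Omega^-1) via the Cholesky factor of Omega^-1, and sets
#' `Y = cbind(1, X) %*% B + E`. Because X is exogenous and B is nonzero, the
#' marginal dependence structure of Y mixes the shared covariate signal with
#' the conditional structure Omega — exactly the confounding that regressing
#' out X is meant to remove.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `X`, `Y` (samples-by-genes matrices with deterministic
#'   identifiers `"s001"...`, `"g0001"...`) and `truth`, a list holding
#'   `precision` (Omega with its `"support"` attribute), `coefficients` (B)
#'   and `support` (two-column matrix of conditional-dependence pairs).
#' @examples
#' d <- generate_dataset(simulation_config(p = 10, n = 8, seed = 42))
#' dim(d$Y)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  p <- cfg$p; q <- cfg$q; n <- cfg$n
  omega <- generate_precision(p, cfg$edge_prob, cfg$noise_partial_corr_range,
                              seed = sub_seed(cfg$seed, "precision"))

  set.seed(sub_seed(cfg$seed, "coefficients"))
  b <- matrix(0, q + 1L, p)
  mask <- rbinom(q * p, 1L, cfg$coef_sparsity) == 1L
  nb <- sum(mask)
  if (nb > 0L) {
    b[-1L, ][mask] <- sample(c(-1, 1), nb, replace = TRUE) * cfg$coef_scale
  }

  set.seed(sub_seed(cfg$seed, "design"))
  x <- matrix(rnorm(n * q), n, q)

  set.seed(sub_seed(cfg$seed, "noise"))
  sigma <- chol2inv(chol(omega))
  e <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
  y <- cbind(1, x) %*% b + e

  gene_ids <- sprintf("g%04d", seq_len(p))
  cov_ids <- if (q == p) gene_ids else sprintf("x%04d", seq_len(q))
  sample_ids <- sprintf("s%03d", seq_len(n))
  dimnames(x) <- list(sample_ids, cov_ids)
  dimnames(y) <- list(sample_ids, gene_ids)
  dimnames(b) <- list(c("(Intercept)", cov_ids), gene_ids)

  list(
    X = x, Y = y,
    truth = list(precision = omega, coefficients = b,
                 support = attr(omega, "support"), config = cfg)
  )
}

#' Derive a gold standard from simulated ground truth
#'
#' Turns the conditional-dependence support of a simulated precision matrix
#' into a directed edge list scorable by [confusion_vs_gold()]. In symmetric
#' mode (the default) each unordered support pair {i, j} becomes the two
#' directed edges (g_i, g_j) and (g_j, g_i); if `tf_ids` is given, only
#' directions whose source is in `tf_ids` are kept.
#'
#' @param truth The `truth` component of [generate_dataset()] output (or any
#'   list with a two-column `support` matrix of index pairs).
#' @param gene_ids Gene identifiers indexed by the support entries.
#' @param tf_ids Optional character vector of designated regulators.
#' @return A `gold_standard` object; its `mode` attribute records whether TF
#'   filtering was applied.
#' @export
derive_gold_standard <- function(truth, gene_ids, tf_ids = NULL) {
  support <- truth$support
  if (is.null(support) || nrow(support) == 0L) {
    edges <- matrix(character(0), 0L, 2L)
  } else {
    a <- gene_ids[support[, 1L]]
    b <- gene_ids[support[, 2L]]
    edges <- rbind(cbind(a, b), cbind(b, a))
    if (!is.null(tf_ids)) {
      edges <- edges[edges[, 1L] %in% tf_ids, , drop = FALSE]
    }
  }
  gs <- gold_standard(edges, gene_universe = gene_ids)
  attr(gs, "mode") <- if (is.null(tf_ids)) "symmetric" else "tf_filtered"
  gs
}
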