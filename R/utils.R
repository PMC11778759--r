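# Internal helpers shared across modules.

# Derive a deterministic per-component seed from a single pipeline seed so
# stages (simulation, bootstrap, fold assignment, ...) consume independent
# substreams and can be rerun in isolation. Kept below 2^31 - 1.
sub_seed <- function(seed, stream) {
  streams <- c(
    precision = 1L, coefficients = 2L, design = 3L, noise = 4L,
    bootstrap = 5L, folds = 6L, split = 7L, gold = 8L
  )
  k <- streams[[stream]]
  as.integer((as.numeric(seed) * 1009 + 7919 * k) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Symmetry check used on weight/precision matrices.
check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stopf("%s must be a square matrix", what)
  }
  if (max(abs(m - t(m))) > tol) {
    stopf("%s is not symmetric (max asymmetry %.3g)", what, max(abs(m - t(m))))
  }
  invisible(m)
}

# jsonlite writer with full precision and unboxed scalars, so that repeated
# runs with identical inputs produce byte-identical artifacts.
write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
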