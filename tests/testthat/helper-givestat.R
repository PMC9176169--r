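# shared fixture builders (all generated in code; no stored data)

rand_spd <- function(n, jitter = 0.5) {
  A <- matrix(rnorm(n * n), n, n)
  S <- crossprod(A) / n + jitter * diag(n)
  (S + t(S)) / 2
}

# a small random regression problem with exogenous errors and its own
# instruments (wald on each regressor) -- the package's bread-and-butter case
rand_problem <- function(n = 40, p = 2, sigma = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- c(1, seq_len(p))
  y <- beta[1] + drop(X %*% beta[-1]) + rnorm(n, sd = sigma)
  data <- regression_data(y, X)
  spec <- do.call(instrument_spec, as.list(setNames(rep("wald", p),
                                                    colnames(X))))
  Z <- build_instrument_matrix(data, spec)
  list(data = data, Z = Z, beta = beta, X = X, y = y)
}

# instrument spec using every regressor as its own (named) instrument,
# so that Z = X and the fit collapses to OLS
self_spec <- function(data) {
  cols <- setdiff(colnames(data$X), "(Intercept)")
  do.call(instrument_spec, as.list(setNames(cols, cols)))
}

expect_rel_equal <- function(actual, expected, tol) {
  scale <- max(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
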