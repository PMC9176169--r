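test_that("centering matrix has its closed form and projection properties", {
  expect_equal(centering_matrix(2), matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  P <- centering_matrix(9)
  expect_equal(drop(P %*% rep(1, 9)), rep(0, 9))
  expect_equal(sum(diag(P)), 8)
  set.seed(1)
  x <- rnorm(9)
  expect_equal(drop(P %*% x), x - mean(x))
  expect_error(centering_matrix(0), class = "give_argument_error")
})

test_that("total sum of squares decomposes exactly and both G^2 forms agree", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    pr <- rand_problem(n = n, p = sample(1:3, 1), sigma = runif(1, 0.5, 3))
    omega <- switch(sample(1:3, 1), NULL, runif(n, 0.5, 2), rand_spd(n))
    g <- give_statistic(iv_fit(pr$data, pr$Z, omega))
    expect_lt(abs(g$ss_regression + g$ss_residual - g$ss_total) /
                g$ss_total, 1e-9)
    expect_lt(abs(g$g2 - g$g2_decomposition) / max(abs(g$g2), 1), 1e-9)
  }
})

test_that("G^2 hits the boundary values in the exact-fit and no-signal cases", {
  set.seed(20)
  n <- 30
  pr <- rand_problem(n = n, p = 2)
  # y exactly in the projected regression span -> residuals 0 -> G^2 = 1
  b <- c(0.5, 2, -1)
  y_span <- drop(quasi_projection(pr$Z) %*% (pr$data$X %*% b))
  fit1 <- iv_fit(regression_data(y_span, pr$X), pr$Z)
  expect_lt(max(abs(fit1$residuals)), 1e-8)
  expect_equal(give_statistic(fit1)$g2, 1, tolerance = 1e-9)
  # y orthogonal to the instruments -> beta_hat = 0 -> u_hat = y -> G^2 = 0
  y0 <- rnorm(n)
  y_orth <- drop(y0 - pr$Z %*% qr.coef(qr(pr$Z), y0))
  fit0 <- iv_fit(regression_data(y_orth, pr$X), pr$Z)
  expect_lt(max(abs(fit0$beta_hat)), 1e-10)
  expect_equal(give_statistic(fit0)$g2, 0, tolerance = 1e-12)
  # constant response -> degenerate
  fitc <- iv_fit(regression_data(rep(2, n) + 0 * y0, pr$X), pr$Z)
  expect_error(give_statistic(fitc), class = "give_degenerate_error")
})

test_that("with Z = X and Omega = I the GIVE statistic is the OLS R-squared", {
  set.seed(30)
  for (i in 1:100) {
    n <- sample(15:80, 1); p <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% runif(p, -2, 2)) + rnorm(n, sd = runif(1, 0.3, 3))
    d <- regression_data(y, X)
    g2 <- give_statistic(iv_fit(d, d$X))$g2
    r2 <- summary(lm(y ~ X))$r.squared
    expect_lt(abs(g2 - r2), 1e-10)
  }
})

test_that("population theta behaves per definition at and between the extremes", {
  S <- matrix(c(2, 1, 1, 3), 2, 2)
  expect_equal(population_theta(c(0, 0), S, 1.5)$value, 0)
  expect_equal(population_theta(c(1, 1), S, 0)$value, 1)
  # beta'S beta = 3, sigma2 = 1 -> 0.75
  expect_equal(population_theta(1, matrix(3), 1)$value, 0.75)
  expect_error(population_theta(c(0, 0), S, 0),
               class = "give_degenerate_error")
  th <- population_theta(c(1, -1), S, 2)$value
  expect_true(th >= 0 && th <= 1)
})

test_that("theta_IV reduces to theta under Z = X limits and converges to moments", {
  S <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  tiv <- population_theta_iv(c(1, 2), S, S, S, 1.2)
  expect_equal(tiv$value, population_theta(c(1, 2), S, 1.2)$value)
  expect_equal(population_theta_iv(c(0, 0), S, S, S, 1)$value, 0)
  expect_error(population_theta_iv(1, matrix(1), matrix(0), matrix(1), 1),
               class = "give_rank_error")
  # large-n plug-in against analytic moments of a joint-normal generator:
  # z = 0.8 x + 0.6 e gives Sigma^Z = diag(1, 0.64) for (intercept, x)
  set.seed(40)
  n <- 100000
  x <- rnorm(n); z <- 0.8 * x + 0.6 * rnorm(n)
  X <- cbind(1, x); Z <- cbind(1, z)
  M <- crossprod(X, Z) %*% solve(crossprod(Z), crossprod(Z, X)) / n
  expect_lt(max(abs(M - diag(c(1, 0.64)))) / 0.64, 0.02)
  beta <- c(1, 2); sigma2 <- 2
  plug <- population_theta_iv(beta, crossprod(X, Z) / n, crossprod(Z) / n,
                              crossprod(Z, X) / n, sigma2)$value
  analytic <- population_theta_iv(beta, rbind(c(1, 0), c(0, 0.8)),
                                  diag(2), rbind(c(1, 0), c(0, 0.8)),
                                  sigma2)$value
  expect_lt(abs(plug - analytic) / analytic, 0.02)
})

test_that("g(a) matches a direct matrix-expression evaluation", {
  set.seed(50)
  # 5-observation instance evaluated against the verbatim formula with an
  # explicit projection matrix
  n <- 5
  X <- cbind(1, rnorm(n)); Z <- cbind(1, rnorm(n)); u <- rnorm(n)
  O <- rand_spd(n)
  a <- c(0.3, -1.2)
  P <- Z %*% solve(t(Z) %*% O %*% Z) %*% t(Z)
  PI <- centering_matrix(n)
  r <- P %*% X %*% a + u
  direct <- drop((t(a) %*% t(X) %*% P %*% (2 * (X %*% a + u) - P %*% X %*% a)) /
                   (t(r) %*% PI %*% r))
  expect_equal(g_function(a, X, Z, O, u), direct, tolerance = 1e-10)
  expect_equal(g_function(c(0, 0), X, Z, O, u), 0)
  # u = 0 with Xa in the instrument span: P X a = X a when Z = X, Omega = I
  a2 <- c(1, 2)
  g0 <- g_function(a2, X, X, NULL, rep(0, n))
  f <- drop(X %*% a2)
  expect_equal(g0, sum(f * f) / sum((f - mean(f)) * f), tolerance = 1e-10)
  # larger random instances
  for (i in 1:10) {
    n <- sample(8:25, 1)
    X <- cbind(1, matrix(rnorm(2 * n), n, 2))
    Z <- cbind(1, matrix(rnorm(2 * n), n, 2))
    u <- rnorm(n); O <- rand_spd(n); a <- rnorm(3)
    P <- Z %*% solve(t(Z) %*% O %*% Z) %*% t(Z)
    r <- drop(P %*% X %*% a + u)
    direct <- drop(t(a) %*% t(X) %*% P %*% (2 * (drop(X %*% a) + u) -
                                              drop(P %*% X %*% a))) /
      drop(t(r) %*% centering_matrix(n) %*% r)
    expect_equal(g_function(a, X, Z, O, u), direct, tolerance = 1e-9)
  }
})

test_that("the finite-difference gradient matches a closed-form derivative", {
  # p = 1, no intercept: g(a) = (A a^2 + B a) / (C a^2 + D a + E)
  set.seed(60)
  n <- 15
  x <- matrix(rnorm(n), n, 1); z <- matrix(durbin_instrument(drop(x)), n, 1)
  u <- rnorm(n); O <- rand_spd(n)
  P <- z %*% solve(t(z) %*% O %*% z) %*% t(z)
  Px <- drop(P %*% x)
  A <- drop(2 * t(x) %*% P %*% x - t(x) %*% P %*% P %*% x)
  B <- drop(2 * t(x) %*% P %*% u)
  C <- sum((Px - mean(Px)) * Px)
  D <- 2 * sum((Px - mean(Px)) * u)
  E <- sum((u - mean(u)) * u)
  dg <- function(a) {
    ((2 * A * a + B) * (C * a^2 + D * a + E) -
       (A * a^2 + B * a) * (2 * C * a + D)) / (C * a^2 + D * a + E)^2
  }
  for (a in c(-1.5, 0.2, 2)) {
    expect_equal(grad_g(a, x, z, O, u), dg(a), tolerance = 1e-6)
  }
  # zero regressor matrix: g is constant, gradient 0
  expect_equal(grad_g(c(1, 2), matrix(0, n, 2), cbind(1, z), O, u), c(0, 0))
})

test_that("central differences converge at second order under step halving", {
  set.seed(61)
  n <- 20
  X <- cbind(1, rnorm(n)); Z <- cbind(1, durbin_instrument(X[, 2]))
  u <- rnorm(n); a <- c(0.5, 1.5)
  ref <- grad_g(a, X, Z, NULL, u, h = 1e-7)
  err <- sapply(c(1e-2, 5e-3, 2.5e-3), function(h)
    max(abs(grad_g(a, X, Z, NULL, u, h = h) - ref)))
  # halving the step shrinks the error ~4x
  expect_gt(err[1] / err[2], 2.5)
  expect_gt(err[2] / err[3], 2.5)
})

test_that("sandwich V collapses correctly, is symmetric, and matches a direct product", {
  set.seed(70)
  n <- 25
  X <- cbind(1, matrix(rnorm(2 * n), n, 2))
  # Omega = I, Z = X -> V = (X'X)^{-1}
  V <- sandwich_v(X, X)
  expect_lt(max(abs(V - solve(crossprod(X)))), 1e-10)
  Z <- cbind(1, durbin_instrument(X[, 2]), wald_instrument(X[, 3]))
  O <- rand_spd(n)
  V2 <- sandwich_v(X, Z, O)
  expect_lt(max(abs(V2 - t(V2))), 1e-10)
  # independent three-factor evaluation with an explicit projection
  P <- Z %*% solve(t(Z) %*% O %*% Z) %*% t(Z)
  XPX <- t(X) %*% P %*% X
  direct <- solve(XPX) %*% (t(X) %*% P %*% O %*% P %*% X) %*% t(solve(XPX))
  expect_lt(max(abs(V2 - direct)) / max(abs(direct)), 1e-8)
  # with the symmetric operator the product collapses to (X'PX)^{-1}
  expect_lt(max(abs(V2 - solve(XPX))) / max(abs(V2)), 1e-8)
})

test_that("standardized statistic vanishes at G^2 = theta and the identity paths agree", {
  set.seed(80)
  pr <- rand_problem(n = 60, p = 2)
  fit <- iv_fit(pr$data, pr$Z)
  g <- give_statistic(fit)
  expect_equal(standardized_give(fit, g$g2), 0, ignore_attr = TRUE)
  t_null <- standardized_give(fit, 0.5)
  fit_id <- iv_fit(pr$data, pr$Z, error_covariance(form = "identity", n = 60))
  t_expl <- standardized_give(fit_id, 0.5)
  expect_identical(as.numeric(t_null), as.numeric(t_expl))
  expect_true(is.finite(attr(t_null, "scale")))
})

test_that("instrument comparison ranks by G^2 and reports failures", {
  set.seed(90)
  n <- 80
  X <- cbind(x = rnorm(n))
  y <- 1 + 2 * X[, 1] + rnorm(n)
  d <- regression_data(y, X)
  named <- cbind(x_self = X[, 1], dup = wald_instrument(X[, 1]))
  cands <- list(self = instrument_spec(x = "x_self"),
                wald = instrument_spec(x = "wald"),
                durbin = instrument_spec(x = "durbin"),
                broken = instrument_spec(x = "missing_col"))
  cmp <- compare_instruments(d, cands, named_columns = named)
  expect_s3_class(cmp, "give_comparison")
  expect_equal(nrow(cmp), 4L)
  # the self-instrumented candidate is OLS: its G^2 is the R^2 and maximal
  r2 <- summary(lm(y ~ X))$r.squared
  expect_equal(cmp$g2[cmp$label == "self"], r2, tolerance = 1e-10)
  expect_equal(cmp$label[1], "self")
  ok <- cmp[cmp$status == "ok", ]
  expect_equal(ok$g2, sort(ok$g2, decreasing = TRUE))
  expect_match(cmp$status[cmp$label == "broken"], "failed")
  # duplicated candidates: identical G^2, stable label order
  cmp2 <- compare_instruments(d, list(a = cands$wald, b = cands$wald))
  expect_equal(cmp2$g2[1], cmp2$g2[2])
  expect_equal(cmp2$label, c("a", "b"))
})

test_that("comparison reports serialize to JSON and aligned text", {
  set.seed(91)
  pr <- rand_problem(n = 40, p = 1)
  cmp <- compare_instruments(pr$data, list(wald = instrument_spec(x1 = "wald"),
                                           durbin = instrument_spec(x1 = "durbin")))
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".txt")
  write_comparison(cmp, jf); write_comparison(cmp, tf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(length(parsed), 2L)
  expect_equal(parsed[[1]]$g2, cmp$g2[1], tolerance = 1e-12)
  expect_equal(readLines(tf)[1], "IV\tGIVE statistic")
})
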