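#' Centering matrix
#'
#' The projection P_I = I_n - (1/n) e e' that removes the mean: symmetric,
#' idempotent, zero row sums, trace n - 1.
#'
#' @param n number of observations (>= 1).
#' @return the n x n centering matrix.
#' @export
centering_matrix <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    give_error("n must be a positive integer", "give_argument_error")
  }
  n <- as.integer(n)
  diag(n) - matrix(1 / n, n, n)
}

# x' P_I y = sum((x - mean(x)) * y), without forming P_I
#' @keywords internal
#' @noRd
center_crossprod <- function(x, y = x) {
  sum((x - mean(x)) * y)
}

#' GIVE statistic of an instrumental-variables fit
#'
#' The Goodness of Instrumental Variable Estimates statistic
#' G^2 = 1 - (u_hat' P_I u_hat) / (y' P_I y), the IV analogue of the
#' coefficient of determination. The centered total sum of squares decomposes
#' as a regression part (a quadratic term in the projected fit plus a
#' cross-term, which in the IV setting need not be orthogonal to the
#' residuals) and a residual part; both the decomposition form and the
#' 1-minus-ratio form are computed and must agree. With Z = X and Omega = I
#' the statistic reduces to the classical OLS R-squared. Because IV fitted
#' values are not an orthogonal projection of y, the statistic can fall
#' outside [0, 1] in finite samples; such values are flagged, never clipped,
#' as they usually signal a poor instrument choice.
#'
#' @param fit an [iv_fit()] object.
#' @return object of class `give_result` with elements `g2` (the 1-ratio
#'   form), `g2_decomposition` (regression-sum form), `ss_regression`,
#'   `ss_residual`, `ss_total`, `out_of_range`, and `theta_plugin` (the
#'   sample plug-in of the population target theta_IV, using X'PX/n and
#'   sigma2_hat; a descriptive quantity, not the population value).
#' @export
give_statistic <- function(fit) {
  if (!inherits(fit, "iv_fit")) {
    give_error("fit must be an iv_fit", "give_argument_error")
  }
  y <- fit$data$y
  u <- fit$residuals
  f <- fit$fitted                      # P X beta_hat
  ss_total <- center_crossprod(y)
  if (ss_total <= 0) {
    give_error("response has zero total variation (constant y)",
               "give_degenerate_error")
  }
  ss_residual <- center_crossprod(u)
  # beta'X'P P_I P X beta + 2 beta'X'P P_I u, written through f = P X beta
  ss_regression <- center_crossprod(f) + 2 * center_crossprod(f, u)
  g2_ratio <- 1 - ss_residual / ss_total
  g2_decomp <- ss_regression / ss_total

  # plug-in theta_IV: beta'(X'PX/n)beta centered, over itself + sigma2_hat
  n <- fit$data$n
  bXPIXb <- center_crossprod(f) / n
  theta_plugin <- bXPIXb / (bXPIXb + fit$sigma2_hat)

  structure(list(g2 = g2_ratio,
                 g2_decomposition = g2_decomp,
                 ss_regression = ss_regression,
                 ss_residual = ss_residual,
                 ss_total = ss_total,
                 out_of_range = (g2_ratio < 0 || g2_ratio > 1),
                 theta_plugin = theta_plugin,
                 std_stat = NULL,
                 n = n),
            class = "give_result")
}

#' @export
print.give_result <- function(x, digits = 7, ...) {
  cat(sprintf("GIVE statistic G^2 = %s%s\n",
              format(signif(x$g2, digits)),
              if (x$out_of_range) "  [outside [0,1] - check instruments]" else ""))
  cat(sprintf("  SS regression = %s, SS residual = %s, SS total = %s\n",
              format(signif(x$ss_regression, digits)),
              format(signif(x$ss_residual, digits)),
              format(signif(x$ss_total, digits))))
  cat(sprintf("  plug-in theta_IV = %s\n", format(signif(x$theta_plugin, digits))))
  if (!is.null(x$std_stat)) {
    cat(sprintf("  standardized statistic = %s\n",
                format(signif(x$std_stat, digits))))
  }
  invisible(x)
}

#' Population goodness-of-fit targets
#'
#' `population_theta()` is the squared population multiple correlation of the
#' classical regression, theta = beta' Sigma beta / (beta' Sigma beta +
#' sigma2), where Sigma is the limit of the centered regressor cross-product
#' X*'P_I X*/n. `population_theta_iv()` is the IV analogue with Sigma replaced
#' by Sigma_XZ Sigma_ZOmegaZ^{-1} Sigma_ZX, the limit of X'P X/n; it is the
#' probability limit of the GIVE statistic. Both lie in [0, 1]: 0 when beta =
#' 0 (no signal), 1 when sigma2 = 0 (noiseless model).
#'
#' @param beta coefficient vector.
#' @param sigma_xstar positive semi-definite limit matrix of the centered
#'   regressor cross-product.
#' @param sigma2 error variance (>= 0).
#' @return object of class `population_theta` with element `value` in [0, 1].
#' @export
population_theta <- function(beta, sigma_xstar, sigma2) {
  beta <- as.numeric(beta)
  S <- as.matrix(sigma_xstar)
  if (sigma2 < 0) give_error("sigma2 must be >= 0", "give_argument_error")
  q <- drop(crossprod(beta, S %*% beta))
  if (q < -1e-10) {
    give_error("sigma_xstar is not positive semi-definite along beta",
               "give_argument_error")
  }
  q <- max(q, 0)
  if (q == 0 && sigma2 == 0) {
    give_error("theta is undefined when both beta'Sigma beta and sigma2 are zero",
               "give_degenerate_error")
  }
  structure(list(value = q / (q + sigma2), beta = beta, sigma2 = sigma2,
                 sigma_xstar = S, kind = "theta"),
            class = "population_theta")
}

#' @rdname population_theta
#' @param sigma_xz limit of X'Z/n.
#' @param sigma_zomegaz limit of Z'Omega Z/n (positive definite).
#' @param sigma_zx limit of Z'X/n.
#' @export
population_theta_iv <- function(beta, sigma_xz, sigma_zomegaz, sigma_zx,
                                sigma2) {
  sigma_xz <- as.matrix(sigma_xz)
  sigma_zomegaz <- as.matrix(sigma_zomegaz)
  sigma_zx <- as.matrix(sigma_zx)
  S <- sigma_xz %*% solve_checked(sigma_zomegaz, sigma_zx,
                                  "give_rank_error", "Sigma_ZOmegaZ")
  S <- (S + t(S)) / 2
  out <- population_theta(beta, S, sigma2)
  out$kind <- "theta_iv"
  out
}

#' @export
print.population_theta <- function(x, digits = 7, ...) {
  cat(sprintf("Population %s = %s\n",
              if (x$kind == "theta_iv") "theta_IV" else "theta",
              format(signif(x$value, digits))))
  invisible(x)
}

#' The asymptotic-variance ingredients of the standardized GIVE statistic
#'
#' `g_function()` evaluates the scalar map
#' g(a) = a'X'P (2(Xa + u) - PXa) / ((PXa + u)' P_I (PXa + u))
#' whose value at the IV estimate, with u replaced by the residuals, is the
#' GIVE statistic expressed as a function of the coefficient; `grad_g()` is
#' its central finite-difference gradient; `sandwich_v()` is the sandwich
#' matrix V = (X'PX)^{-1} (X'P Omega P X) (X'PX)^{-T}. With the symmetric
#' projection P = Z(Z'Omega Z)^{-1} Z' the middle factor collapses and V =
#' (X'PX)^{-1}; the three-factor product is nevertheless computed as written
#' so the identity can be verified and the omega-weighted variant supported.
#'
#' @param a coefficient vector at which to evaluate.
#' @param X regressor matrix (including intercept column when the model has
#'   one).
#' @param Z instrument matrix.
#' @param omega error covariance (see [error_covariance()]); `NULL` = identity.
#' @param u error vector; in practice the fit residuals stand in for the
#'   unobservable errors.
#' @return `g_function()`: a scalar; `grad_g()`: a vector of length
#'   `length(a)`; `sandwich_v()`: a symmetric positive semi-definite matrix.
#' @export
g_function <- function(a, X, Z, omega = NULL, u) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  a <- as.numeric(a); u <- as.numeric(u)
  omega <- as_error_covariance(omega, nrow(Z))
  Xa <- drop(X %*% a)
  PXa <- drop(pz_apply(Z, omega, Xa))
  num <- sum(PXa * (2 * (Xa + u) - PXa))   # a'X'P(...) via symmetric P
  r <- PXa + u
  den <- center_crossprod(r)
  if (abs(den) < .Machine$double.eps * max(1, sum(r^2))) {
    give_error("g(a) denominator is zero (degenerate centered sum of squares)",
               "give_degenerate_error")
  }
  num / den
}

#' @rdname g_function
#' @param h optional fixed step; by default the per-coordinate step is
#'   `1e-6 * max(1, |a_j|)`.
#' @export
grad_g <- function(a, X, Z, omega = NULL, u, h = NULL) {
  a <- as.numeric(a)
  d <- length(a)
  g <- numeric(d)
  for (j in seq_len(d)) {
    hj <- if (is.null(h)) 1e-6 * max(1, abs(a[j])) else h
    ap <- a; ap[j] <- a[j] + hj
    am <- a; am[j] <- a[j] - hj
    gp <- g_function(ap, X, Z, omega, u)
    gm <- g_function(am, X, Z, omega, u)
    if (!is.finite(gp) || !is.finite(gm)) {
      give_error("g(a) is non-finite near a; cannot differentiate",
                 "give_degenerate_error")
    }
    g[j] <- (gp - gm) / (2 * hj)
  }
  g
}

#' @rdname g_function
#' @export
sandwich_v <- function(X, Z, omega = NULL) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  omega <- as_error_covariance(omega, nrow(Z))
  PX <- pz_apply(Z, omega, X)
  XPX <- crossprod(X, PX)
  mid <- crossprod(PX, omega_mult(omega, PX))   # X'P Omega P X
  Ainv_mid <- solve_checked(XPX, mid, "give_rank_error", "X'PX")
  V <- t(solve_checked(t(XPX), t(Ainv_mid), "give_rank_error", "X'PX"))
  (V + t(V)) / 2
}

#' Standardized GIVE statistic
#'
#' The asymptotic standardization of the deviation of the GIVE statistic from
#' its population target: T = sqrt(n) * s * (G^2 - theta) with
#' s = grad_g(a)' V grad_g(a) evaluated at the IV estimate, the scaling
#' written with the variance factor multiplying the deviation. The identity
#' Omega path is the same formula with Omega = I, so passing an identity
#' covariance reproduces the spherical-error special case exactly. Note that
#' because V is built from un-normalized cross-products (X'PX is of order n),
#' the multiplicative factor s shrinks like 1/n; see the methods vignette for
#' a discussion of the finite-sample behaviour of this form.
#'
#' @param g2 a [give_statistic()] result (or a bare numeric G^2 value).
#' @param theta the population target theta_IV (a [population_theta()] object
#'   or bare numeric).
#' @param n sample size.
#' @inheritParams g_function
#' @param u_hat residual vector standing in for the unobservable errors.
#' @param beta coefficient vector at which the gradient is evaluated: the IV
#'   estimate from the same fit that produced `g2` and `u_hat`.
#' @return scalar T, with attributes `scale` (the factor s) and `gradient`.
#' @export
standardized_statistic <- function(g2, theta, n, X, Z, omega = NULL, u_hat,
                                   beta) {
  g2v <- if (inherits(g2, "give_result")) g2$g2 else as.numeric(g2)
  thv <- if (inherits(theta, "population_theta")) theta$value
         else as.numeric(theta)
  X <- as.matrix(X); Z <- as.matrix(Z)
  omega <- as_error_covariance(omega, nrow(Z))
  grad <- grad_g(beta, X, Z, omega, u_hat)
  V <- sandwich_v(X, Z, omega)
  s <- drop(crossprod(grad, V %*% grad))
  if (!is.finite(s)) {
    give_error("standardization factor is non-finite", "give_degenerate_error")
  }
  out <- sqrt(n) * s * (g2v - thv)
  attr(out, "scale") <- s
  attr(out, "gradient") <- grad
  out
}

#' @rdname standardized_statistic
#' @param fit an [iv_fit()]; its residuals, instrument matrix and Omega are
#'   used, and g is differentiated at its coefficient estimate.
#' @export
standardized_give <- function(fit, theta) {
  g2 <- give_statistic(fit)
  standardized_statistic(g2, theta, fit$data$n, fit$data$X, fit$Z,
                         fit$omega, fit$residuals, fit$beta_hat)
}

#' Rank instrument choices by goodness of fit
#'
#' Fits the model once per candidate instrument specification and tabulates
#' the GIVE statistic of each, sorted by G^2 in decreasing order (ties broken
#' by label) so the best-fitting instrument choice tops the table. A candidate
#' whose fit fails (e.g. non-identification) is reported with its error
#' message rather than dropped. No multiplicity adjustment is applied: the
#' comparison is a descriptive ranking, not a test.
#'
#' @param data a [regression_data()] object.
#' @param candidates named list of [instrument_spec()] objects (names are the
#'   report labels; an unnamed entry uses its spec label).
#' @param omega error covariance shared by all candidates; `NULL` = identity.
#' @param named_columns table of named instrument columns for specs that
#'   reference them.
#' @return object of class `give_comparison`: a data frame with columns
#'   `label`, `g2`, `theta_plugin`, `out_of_range`, `status`, plus a
#'   `coefficients` list column, ordered by decreasing `g2`.
#' @export
compare_instruments <- function(data, candidates, omega = NULL,
                                named_columns = NULL) {
  if (!length(candidates)) {
    give_error("no candidate instrument specifications", "give_argument_error")
  }
  labels <- names(candidates)
  if (is.null(labels)) labels <- rep("", length(candidates))
  for (i in seq_along(candidates)) {
    if (!nzchar(labels[i])) {
      labels[i] <- if (!is.null(candidates[[i]]$label)) candidates[[i]]$label
                   else sprintf("candidate%d", i)
    }
  }
  rows <- lapply(seq_along(candidates), function(i) {
    res <- tryCatch({
      Z <- build_instrument_matrix(data, candidates[[i]], named_columns)
      fit <- iv_fit(data, Z, omega)
      gr <- give_statistic(fit)
      list(g2 = gr$g2, theta_plugin = gr$theta_plugin,
           out_of_range = gr$out_of_range, status = "ok",
           coefficients = fit$beta_hat)
    }, give_error = function(e) {
      list(g2 = NA_real_, theta_plugin = NA_real_, out_of_range = NA,
           status = paste0("failed: ", conditionMessage(e)),
           coefficients = NULL)
    })
    res$label <- labels[i]
    res
  })
  df <- data.frame(
    label = vapply(rows, `[[`, character(1), "label"),
    g2 = vapply(rows, `[[`, numeric(1), "g2"),
    theta_plugin = vapply(rows, `[[`, numeric(1), "theta_plugin"),
    out_of_range = vapply(rows, `[[`, logical(1), "out_of_range"),
    status = vapply(rows, `[[`, character(1), "status"),
    stringsAsFactors = FALSE
  )
  df$coefficients <- lapply(rows, `[[`, "coefficients")
  ord <- order(-ifelse(is.na(df$g2), -Inf, df$g2), df$label)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("give_comparison", class(df))
  df
}

#' @export
print.give_comparison <- function(x, digits = 7, ...) {
  cat("Instrument comparison (GIVE statistic, best fit first)\n")
  tab <- data.frame(IV = x$label,
                    `GIVE statistic` = signif(x$g2, digits),
                    status = x$status, check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize a comparison report
#'
#' @param x a `give_comparison`.
#' @param path output file; JSON when it ends in `.json`, aligned text
#'   otherwise.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  if (grepl("\\.json$", path)) {
    payload <- lapply(seq_len(nrow(x)), function(i) {
      list(label = x$label[i],
           g2 = x$g2[i],
           theta_plugin = x$theta_plugin[i],
           out_of_range = x$out_of_range[i],
           status = x$status[i],
           coefficients = as.list(x$coefficients[[i]]))
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    lines <- c("IV\tGIVE statistic",
               sprintf("%s\t%.7g", x$label, x$g2))
    writeLines(lines, path)
  }
  invisible(path)
}
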