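#' Regression data container
#'
#' Holds the response vector and regressor matrix of the linear model
#' y = X beta + u with non-spherical disturbances E(uu') = sigma^2 Omega^{-1}.
#' When `intercept = TRUE` a leading column of ones named `"(Intercept)"` is
#' prepended (unless already present), mirroring the convention that the model
#' carries an intercept term alongside p substantive regressors.
#'
#' @param y numeric response vector of length n.
#' @param X numeric matrix of regressors (n rows). Column names are kept; if
#'   absent, `x1 ... xp` are assigned.
#' @param intercept logical; add/expect an intercept column.
#' @return object of class `regression_data` with elements `y`, `X` (including
#'   the intercept column when requested), `has_intercept`, `n`, `p` (number of
#'   non-intercept regressors).
#' @export
regression_data <- function(y, X, intercept = TRUE) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X)) {
    give_error("length(y) must equal nrow(X)", "give_argument_error")
  }
  stopifnot_finite(y, "y"); stopifnot_finite(X, "X")
  has_ones <- ncol(X) > 0 && all(X[, 1L] == 1)
  if (intercept && !has_ones) {
    X <- cbind("(Intercept)" = 1, X)
  } else if (intercept && has_ones) {
    colnames(X)[1L] <- "(Intercept)"
  }
  n <- length(y)
  p <- ncol(X) - as.integer(intercept)
  if (n <= ncol(X)) {
    give_error("need more observations than regressor columns",
               "give_argument_error")
  }
  structure(list(y = y, X = X, has_intercept = isTRUE(intercept),
                 n = n, p = p),
            class = "regression_data")
}

#' @export
print.regression_data <- function(x, ...) {
  cat(sprintf("Regression data: n = %d, p = %d regressor(s)%s\n", x$n, x$p,
              if (x$has_intercept) " + intercept" else ""))
  invisible(x)
}

#' Error covariance specification
#'
#' Represents the Omega of the disturbance covariance E(uu') = sigma^2
#' Omega^{-1}: a known or estimated symmetric positive-definite matrix. To
#' keep large-n fits cheap, identity and diagonal forms are stored implicitly
#' (no n x n matrix is materialized); the full form stores the matrix.
#'
#' @param omega for `form = "full"` an n x n symmetric positive-definite
#'   matrix; for `form = "diagonal"` the vector of positive diagonal entries;
#'   ignored for `form = "identity"`.
#' @param form one of `"identity"`, `"diagonal"`, `"full"`.
#' @param source `"known"` or `"estimated"`.
#' @param n sample size (required for `"identity"` when `omega` is missing).
#' @return object of class `error_covariance`.
#' @export
error_covariance <- function(omega = NULL,
                             form = c("identity", "diagonal", "full"),
                             source = c("known", "estimated"),
                             n = NULL) {
  form <- match.arg(form)
  source <- match.arg(source)
  if (form == "identity") {
    if (is.null(n) && !is.null(omega)) n <- NROW(omega)
    if (is.null(n)) give_error("identity form needs n", "give_argument_error")
    obj <- list(form = form, source = source, n = as.integer(n), w = NULL,
                m = NULL)
  } else if (form == "diagonal") {
    w <- as.numeric(omega)
    stopifnot_finite(w, "omega diagonal")
    if (any(w <= 0)) {
      give_error("diagonal Omega must have strictly positive entries",
                 "give_argument_error")
    }
    obj <- list(form = form, source = source, n = length(w), w = w, m = NULL)
  } else {
    m <- as.matrix(omega)
    stopifnot_finite(m, "omega")
    if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
      give_error("Omega must be symmetric", "give_argument_error")
    }
    m <- (m + t(m)) / 2
    ev_min <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 0) {
      give_error("Omega must be positive definite", "give_argument_error")
    }
    obj <- list(form = form, source = source, n = nrow(m), w = NULL, m = m)
  }
  structure(obj, class = "error_covariance")
}

#' @export
print.error_covariance <- function(x, ...) {
  cat(sprintf("Error covariance Omega: %s form (%s), n = %d\n",
              x$form, x$source, x$n))
  invisible(x)
}

#' @keywords internal
#' @noRd
as_error_covariance <- function(omega, n) {
  if (is.null(omega)) return(error_covariance(form = "identity", n = n))
  if (inherits(omega, "error_covariance")) {
    if (omega$n != n) {
      give_error("Omega dimension does not match the data", "give_argument_error")
    }
    return(omega)
  }
  if (is.matrix(omega)) return(error_covariance(omega, form = "full"))
  if (is.numeric(omega) && length(omega) == n) {
    return(error_covariance(omega, form = "diagonal"))
  }
  give_error("cannot interpret omega", "give_argument_error")
}

# Omega %*% M without materializing identity/diagonal Omega
#' @keywords internal
#' @noRd
omega_mult <- function(omega, M) {
  switch(omega$form,
         identity = M,
         diagonal = omega$w * M,
         full     = omega$m %*% M)
}

# Z' Omega M
#' @keywords internal
#' @noRd
omega_crossprod <- function(Z, omega, M = Z) {
  crossprod(Z, omega_mult(omega, M))
}

#' @keywords internal
#' @noRd
solve_checked <- function(A, b, error_class, what) {
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-12) {
    give_error(sprintf("%s is numerically singular (rcond = %.3g)", what, rc),
               error_class)
  }
  solve(A, b)
}

# P_ZOmega %*% M = Z (Z'Omega Z)^{-1} Z' M, computed without forming the
# n x n projection ("printed" operator). The "omega_weighted" variant appends
# a trailing Omega: Z (Z'Omega Z)^{-1} Z' Omega M, which is the first-stage
# fitted-value operator.
#' @keywords internal
#' @noRd
pz_apply <- function(Z, omega, M, variant = "printed") {
  ZOZ <- omega_crossprod(Z, omega)
  rhs <- if (variant == "printed") crossprod(Z, M)
         else crossprod(Z, omega_mult(omega, M))
  Z %*% solve_checked(ZOZ, rhs, "give_rank_error", "Z'OmegaZ")
}

#' Quasi-projection onto the instrument space
#'
#' The operator P = Z (Z' Omega Z)^{-1} Z' used by the two-stage feasible GLS
#' estimator. It is symmetric and satisfies P Omega P = P; at Omega = I it is
#' the ordinary idempotent hat matrix of Z with trace equal to the number of
#' instrument columns. The `"omega_weighted"` variant returns
#' Z (Z' Omega Z)^{-1} Z' Omega, the (generally non-symmetric) operator whose
#' action on X gives the first-stage fitted values; it coincides with the
#' default at Omega = I.
#'
#' @param Z instrument matrix (n x q).
#' @param omega an [error_covariance()], a diagonal vector, a full matrix, or
#'   `NULL` for identity.
#' @param variant `"printed"` (default, symmetric) or `"omega_weighted"`.
#' @return the n x n projection matrix. Intended for inspection and small-n
#'   work; the fitting routines apply the operator in factored form and never
#'   build it.
#' @export
quasi_projection <- function(Z, omega = NULL,
                             variant = c("printed", "omega_weighted")) {
  variant <- match.arg(variant)
  Z <- as.matrix(Z)
  omega <- as_error_covariance(omega, nrow(Z))
  pz_apply(Z, omega, diag(nrow(Z)), variant = variant)
}

#' First-stage feasible GLS regression of X on Z
#'
#' Computes alpha_hat = (Z' Omega Z)^{-1} Z' Omega X, the generalized
#' least-squares coefficient of each regressor column on the instruments, and
#' the fitted values X_hat = Z alpha_hat. At Omega = I this reduces to
#' column-wise ordinary least squares.
#'
#' @inheritParams quasi_projection
#' @param X regressor matrix (n x k).
#' @return list with `alpha_hat` (q x k) and `fitted` (n x k).
#' @export
first_stage <- function(X, Z, omega = NULL) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (nrow(X) != nrow(Z)) {
    give_error("X and Z must have the same number of rows", "give_argument_error")
  }
  omega <- as_error_covariance(omega, nrow(Z))
  ZOZ <- omega_crossprod(Z, omega)
  alpha_hat <- solve_checked(ZOZ, omega_crossprod(Z, omega, X),
                             "give_rank_error", "Z'OmegaZ")
  dimnames(alpha_hat) <- list(colnames(Z), colnames(X))
  list(alpha_hat = alpha_hat, fitted = Z %*% alpha_hat)
}

#' Two-stage feasible GLS instrumental-variables fit
#'
#' Computes the estimator beta_hat = (X' P X)^{-1} X' P y with
#' P = Z (Z' Omega Z)^{-1} Z', its residuals u_hat = y - P X beta_hat, and the
#' first stage. With Z = X and Omega = I the estimator reduces to ordinary
#' least squares; with as many instruments as regressors it reduces to the
#' classical just-identified IV estimator (Z'X)^{-1} Z'y; and beta_hat is
#' invariant to rescaling Omega.
#'
#' @param data a [regression_data()] object.
#' @param Z instrument matrix with as many columns as `data$X` (a plain matrix
#'   or [build_instrument_matrix()] output).
#' @param omega error covariance (see [error_covariance()]); `NULL` = identity.
#' @param projection `"printed"` uses the symmetric operator
#'   Z (Z'Omega Z)^{-1} Z' throughout; `"omega_weighted"` uses the
#'   first-stage fitted-value operator with a trailing Omega instead. The two
#'   coincide at Omega = I.
#' @return object of class `iv_fit`: `beta_hat`, `residuals`, `fitted`
#'   (`fitted + residuals == y` by construction), `alpha_hat`, `sigma2_hat`
#'   (= u_hat'u_hat / (n - k)), plus the inputs needed downstream.
#' @export
iv_fit <- function(data, Z, omega = NULL,
                   projection = c("printed", "omega_weighted")) {
  projection <- match.arg(projection)
  if (!inherits(data, "regression_data")) {
    give_error("data must be a regression_data object", "give_argument_error")
  }
  Z <- as.matrix(Z)
  if (nrow(Z) != data$n) {
    give_error("Z must have n rows", "give_argument_error")
  }
  if (ncol(Z) != ncol(data$X)) {
    give_error("Z must have the same column count as X (including intercept)",
               "give_argument_error")
  }
  omega <- as_error_covariance(omega, data$n)
  X <- data$X; y <- data$y
  fs <- first_stage(X, Z, omega)

  PX <- pz_apply(Z, omega, X, variant = projection)      # P X (n x k)
  Py <- pz_apply(Z, omega, y, variant = projection)      # P y (n)
  XPX <- crossprod(X, PX)
  XPy <- crossprod(X, Py)
  beta_hat <- tryCatch(
    drop(solve_checked(XPX, XPy, "give_identification_error", "X'PX")),
    give_identification_error = function(e) {
      give_error(paste0("instruments do not identify all coefficients: ",
                        conditionMessage(e)),
                 "give_identification_error")
    })
  names(beta_hat) <- colnames(X)
  fitted <- drop(PX %*% beta_hat)
  residuals <- y - fitted
  k <- ncol(X)
  sigma2_hat <- sum(residuals^2) / (data$n - k)

  structure(list(beta_hat = beta_hat,
                 residuals = residuals,
                 fitted = fitted,
                 alpha_hat = fs$alpha_hat,
                 sigma2_hat = sigma2_hat,
                 projection = projection,
                 PX = PX,
                 data = data, Z = Z, omega = omega),
            class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, digits = 7, ...) {
  cat(sprintf("Two-stage feasible GLS IV fit (n = %d, %s projection, Omega: %s)\n",
              x$data$n, x$projection, x$omega$form))
  cat("Coefficients:\n")
  print(signif(x$beta_hat, digits))
  cat(sprintf("sigma2_hat = %s\n", format(signif(x$sigma2_hat, digits))))
  invisible(x)
}

#' @export
coef.iv_fit <- function(object, ...) object$beta_hat

#' @export
residuals.iv_fit <- function(object, ...) object$residuals

#' @export
fitted.iv_fit <- function(object, ...) object$fitted

#' Feasible diagonal estimate of Omega
#'
#' One-iteration feasible estimator of a diagonal Omega from the data: fit the
#' first stage under identity weighting, average the squared first-stage
#' residuals across regressor columns to get a per-observation dispersion,
#' smooth it by regressing on the instruments (linear projection, floored at a
#' small positive fraction of its mean to keep Omega positive definite), and
#' invert: Omega_hat = diag(1 / v_hat). Since E(uu') = sigma^2 Omega^{-1},
#' large estimated dispersion means a small Omega weight. Omega is only
#' identified up to scale and the fit is invariant to that scale.
#'
#' @param data a [regression_data()] object.
#' @param Z instrument matrix.
#' @return an [error_covariance()] of diagonal form, `source = "estimated"`.
#' @export
estimate_omega <- function(data, Z) {
  Z <- as.matrix(Z)
  fs <- first_stage(data$X, Z, NULL)
  E <- data$X - fs$fitted
  v <- rowMeans(E^2)
  # smooth against Z to damp per-row noise
  sm <- stats::lm.fit(Z, v)$fitted.values
  floor_v <- 0.05 * mean(v)
  v_hat <- pmax(sm, floor_v)
  w <- 1 / v_hat
  # Omega is identified only up to scale; fix trace(Omega) = n so that the
  # homoskedastic case returns ~identity. The projection Z(Z'Omega Z)^{-1}Z'
  # is written without a trailing Omega, so although beta_hat is invariant to
  # the scale of Omega, fitted values and residuals are not; a canonical
  # normalization keeps them meaningful.
  w <- w * length(w) / sum(w)
  error_covariance(w, form = "diagonal", source = "estimated")
}

#' Sample-analogue diagnostics for the IV assumptions
#'
#' Reports the empirical counterparts of the instrument validity and relevance
#' conditions: the norm of Z'u_hat/n (instrument exogeneity), the smallest
#' singular values of Z'X/n, X'X/n and Z'Z/n (relevance / nondegeneracy) and
#' their condition numbers. Values below the thresholds are flagged.
#'
#' @param fit an [iv_fit()] object.
#' @param Z optional instrument matrix to diagnose against the fit's
#'   residuals (e.g. a candidate set with extra columns); defaults to the
#'   fit's own instruments.
#' @param exogeneity_tol flag when `||Z'u_hat/n|| >=` this value.
#' @param relevance_tol flag when a smallest singular value is below this.
#' @return object of class `iv_diagnostics` (a list of named measures and a
#'   logical `flags` vector).
#' @export
assumption_diagnostics <- function(fit, Z = NULL, exogeneity_tol = 0.1,
                                   relevance_tol = 1e-8) {
  if (!inherits(fit, "iv_fit")) {
    give_error("fit must be an iv_fit", "give_argument_error")
  }
  n <- fit$data$n
  if (is.null(Z)) Z <- fit$Z
  X <- fit$data$X
  zu <- drop(crossprod(Z, fit$residuals)) / n
  sv <- function(M) svd(M, nu = 0, nv = 0)$d
  d_zx <- sv(crossprod(Z, X) / n)
  d_xx <- sv(crossprod(X) / n)
  d_zz <- sv(crossprod(Z) / n)
  out <- list(
    zu_norm = sqrt(sum(zu^2)),
    zu = zu,
    min_sv = c(ZX = min(d_zx), XX = min(d_xx), ZZ = min(d_zz)),
    condition = c(ZX = max(d_zx) / min(d_zx),
                  XX = max(d_xx) / min(d_xx),
                  ZZ = max(d_zz) / min(d_zz)),
    exogeneity_tol = exogeneity_tol,
    relevance_tol = relevance_tol
  )
  out$flags <- c(exogeneity = out$zu_norm >= exogeneity_tol,
                 relevance_ZX = out$min_sv[["ZX"]] < relevance_tol,
                 rank_XX = out$min_sv[["XX"]] < relevance_tol,
                 rank_ZZ = out$min_sv[["ZZ"]] < relevance_tol)
  structure(out, class = "iv_diagnostics")
}

#' @export
print.iv_diagnostics <- function(x, ...) {
  cat("IV assumption diagnostics (sample analogues)\n")
  cat(sprintf("  ||Z'u_hat/n||      : %.6g %s\n", x$zu_norm,
              if (x$flags[["exogeneity"]]) "[FLAG]" else ""))
  for (nm in names(x$min_sv)) {
    cat(sprintf("  min sv %s/n        : %.6g (cond %.3g)%s\n", nm,
                x$min_sv[[nm]], x$condition[[nm]],
                if (x$min_sv[[nm]] < x$relevance_tol) " [FLAG]" else ""))
  }
  invisible(x)
}
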