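#' Grouping instruments for a single regressor
#'
#' Classical instruments constructed from the order statistics of a regressor:
#' the Wald instrument splits observations at the median and codes the two
#' groups -1/+1; the Durbin instrument uses the ranks of the observations
#' (average ranks for ties); the Bartlett instrument splits the sorted
#' observations into three groups coded -1/0/+1. All three are (by
#' construction) correlated with the regressor but, unlike the regressor
#' itself, depend on it only through its ordering, which is what makes them
#' usable as instruments when the regressor is contaminated by measurement
#' error.
#'
#' @param x numeric vector of observations on one regressor. Must not be
#'   constant: a constant regressor produces a constant instrument and a
#'   singular instrument cross-product.
#' @return `wald_instrument()`: a vector in \{-1, +1\} (values `<=` the median
#'   are coded -1); `durbin_instrument()`: the vector of ranks (ties receive
#'   average ranks, so the output always sums to n(n+1)/2);
#'   `bartlett_instrument()`: a vector in \{-1, 0, +1\} where the lowest
#'   `ceiling(n/3)` observations (by value, ties broken by original index)
#'   are coded -1 and the highest `ceiling(n/3)` are coded +1.
#' @examples
#' wald_instrument(c(1, 2, 3, 4))
#' durbin_instrument(c(1, 2, 2, 4))
#' bartlett_instrument(c(6, 1, 3))
#' @export
wald_instrument <- function(x) {
  x <- as.numeric(x)
  stopifnot_finite(x, "x")
  if (length(x) < 2L) {
    give_error("Wald instrument needs at least 2 observations",
               "give_argument_error")
  }
  z <- ifelse(x <= stats::median(x), -1, 1)
  if (all(z == z[1L])) {
    give_error(paste0("degenerate median split: all observations fall in one ",
                      "group (constant or near-constant regressor), the Wald ",
                      "instrument would be constant and Z'Z singular"),
               "give_degenerate_error")
  }
  z
}

#' @rdname wald_instrument
#' @export
durbin_instrument <- function(x) {
  x <- as.numeric(x)
  stopifnot_finite(x, "x")
  if (length(x) < 1L) {
    give_error("empty regressor", "give_argument_error")
  }
  if (length(unique(x)) == 1L) {
    give_error("constant regressor: the rank instrument would be constant",
               "give_degenerate_error")
  }
  rank(x, ties.method = "average")
}

#' @rdname wald_instrument
#' @export
bartlett_instrument <- function(x) {
  x <- as.numeric(x)
  stopifnot_finite(x, "x")
  n <- length(x)
  if (n < 3L) {
    give_error("Bartlett instrument needs at least 3 observations",
               "give_argument_error")
  }
  if (length(unique(x)) == 1L) {
    give_error("constant regressor: the three-group instrument is undefined",
               "give_degenerate_error")
  }
  k <- ceiling(n / 3)
  ord <- order(x, seq_along(x))   # ties broken by original index
  z <- numeric(n)
  z[ord[seq_len(k)]] <- -1
  z[ord[seq.int(n - k + 1L, n)]] <- 1
  z
}

#' Instrument specification for a regressor matrix
#'
#' Describes, column by column, how the instrument matrix Z is assembled from
#' a regressor matrix X: each non-intercept regressor is mapped either to one
#' of the generated grouping instruments (`"wald"`, `"durbin"`, `"bartlett"`)
#' or to a named external instrument column supplied separately. The intercept
#' column, when present, is always its own instrument (a column of ones);
#' grouping transforms are never applied to it.
#'
#' @param ... named arguments, one per non-intercept regressor column: the
#'   value is `"wald"`, `"durbin"` or `"bartlett"` for a generated instrument,
#'   or any other string naming a column of the `named_columns` table passed
#'   to [build_instrument_matrix()].
#' @param include_intercept logical; whether the assembled Z carries a leading
#'   column of ones.
#' @param label optional label used in comparison reports.
#' @return an object of class `instrument_spec`.
#' @examples
#' instrument_spec(x1 = "wald", x2 = "durbin")
#' instrument_spec(educ = "nearc4", label = "college proximity")
#' @export
instrument_spec <- function(..., include_intercept = TRUE, label = NULL) {
  map <- list(...)
  if (length(map) == 0L) {
    give_error("instrument_spec needs at least one regressor mapping",
               "give_spec_error")
  }
  if (is.null(names(map)) || any(!nzchar(names(map)))) {
    give_error("every instrument mapping must be named after a regressor column",
               "give_spec_error")
  }
  if (anyDuplicated(names(map))) {
    give_error("a regressor column is mapped to more than one instrument source",
               "give_spec_error")
  }
  ok <- vapply(map, function(v) is.character(v) && length(v) == 1L, logical(1))
  if (!all(ok)) {
    give_error("instrument mappings must be single strings", "give_spec_error")
  }
  structure(
    list(column_map = vapply(map, identity, character(1)),
         include_intercept = isTRUE(include_intercept),
         label = label),
    class = "instrument_spec"
  )
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat("Instrument specification",
      if (!is.null(x$label)) sprintf("[%s]", x$label) else "", "\n")
  cat(sprintf("  intercept instrument: %s\n",
              if (x$include_intercept) "column of ones" else "none"))
  for (nm in names(x$column_map)) {
    src <- x$column_map[[nm]]
    kind <- if (src %in% c("wald", "durbin", "bartlett")) {
      sprintf("%s (generated)", src)
    } else {
      sprintf("named column '%s'", src)
    }
    cat(sprintf("  %s -> %s\n", nm, kind))
  }
  invisible(x)
}

#' Assemble an instrument matrix
#'
#' Builds the instrument matrix Z column-by-column from a regressor matrix
#' following an [instrument_spec()]: generated instruments are computed from
#' the corresponding regressor column, named instruments are copied from
#' `named_columns`. Z has the same column count as X (including the intercept
#' column of ones when requested) and its cross-product is checked for
#' numerical rank; a rank deficiency is reported naming the offending columns.
#'
#' @param X numeric regressor matrix (without intercept column; the intercept
#'   instrument is appended by the spec), or a [regression_data()] object, in
#'   which case its non-intercept columns are used and the intercept setting
#'   is taken from the data.
#' @param spec an [instrument_spec()].
#' @param named_columns optional data frame / matrix holding named instrument
#'   columns referenced by the spec; must have as many rows as X.
#' @return an object of class `instrument_matrix`: the numeric matrix Z with
#'   a `provenance` attribute labelling each column (e.g. `"Z1 (wald)"`).
#' @export
build_instrument_matrix <- function(X, spec, named_columns = NULL) {
  if (inherits(X, "regression_data")) {
    if (spec$include_intercept != X$has_intercept) {
      give_error("instrument spec and regression data disagree about the intercept",
                 "give_spec_error")
    }
    X <- X$X[, setdiff(colnames(X$X), "(Intercept)"), drop = FALSE]
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!inherits(spec, "instrument_spec")) {
    give_error("spec must be an instrument_spec", "give_spec_error")
  }
  missing_cols <- setdiff(colnames(X), names(spec$column_map))
  if (length(missing_cols) > 0L) {
    give_error(sprintf("regressor column(s) not mapped to any instrument: %s",
                       paste(missing_cols, collapse = ", ")),
               "give_spec_error")
  }
  unknown <- setdiff(names(spec$column_map), colnames(X))
  if (length(unknown) > 0L) {
    give_error(sprintf("spec maps unknown regressor column(s): %s",
                       paste(unknown, collapse = ", ")),
               "give_spec_error")
  }
  n <- nrow(X)
  cols <- list()
  prov <- character(0)
  if (spec$include_intercept) {
    cols <- c(cols, list(rep(1, n)))
    prov <- c(prov, "Z0 (intercept)")
  }
  for (j in seq_along(colnames(X))) {
    nm <- colnames(X)[j]
    src <- spec$column_map[[nm]]
    zj <- switch(src,
      wald     = wald_instrument(X[, nm]),
      durbin   = durbin_instrument(X[, nm]),
      bartlett = bartlett_instrument(X[, nm]),
      {
        if (is.null(named_columns) || !(src %in% colnames(named_columns))) {
          give_error(sprintf("named instrument column '%s' (for regressor '%s') not found",
                             src, nm), "give_spec_error")
        }
        if (nrow(named_columns) != n) {
          give_error("named instrument columns must have as many rows as X",
                     "give_spec_error")
        }
        as.numeric(named_columns[, src, drop = TRUE])
      })
    cols <- c(cols, list(zj))
    prov <- c(prov, sprintf("Z%d (%s%s)", j,
                            if (src %in% c("wald", "durbin", "bartlett")) src
                            else paste0("named: ", src),
                            ""))
  }
  Z <- do.call(cbind, cols)
  colnames(Z) <- vapply(strsplit(prov, " "), `[[`, character(1), 1L)
  check_instrument_rank(Z, prov)
  structure(Z, provenance = prov, class = c("instrument_matrix", class(Z)))
}

#' @keywords internal
#' @noRd
check_instrument_rank <- function(Z, prov = colnames(Z)) {
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- qz$pivot[seq.int(qz$rank + 1L, ncol(Z))]
    give_error(sprintf("instrument matrix is collinear; offending column(s): %s",
                       paste(prov[bad], collapse = ", ")),
               "give_collinearity_error")
  }
  invisible(TRUE)
}

#' @export
print.instrument_matrix <- function(x, ...) {
  cat(sprintf("Instrument matrix: %d observations x %d instruments\n",
              nrow(x), ncol(x)))
  for (p in attr(x, "provenance")) cat("  ", p, "\n")
  invisible(x)
}
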