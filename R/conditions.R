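#' @keywords internal
#' @noRd
give_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "give_error"), call = call))
}

# error subclasses used across the package:
#   give_argument_error      invalid argument values / shapes
#   give_degenerate_error    constant input, zero denominator, zero variation
#   give_spec_error          incomplete or inconsistent instrument spec
#   give_collinearity_error  numerically singular Z'Z / Z'OmegaZ
#   give_rank_error          singular Z'OmegaZ in projection / first stage
#   give_identification_error singular X'PX (instruments do not identify beta)
#   give_schema_error        table does not match the declared schema

#' @keywords internal
#' @noRd
stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    give_error(sprintf("%s contains non-finite values", what),
               "give_argument_error")
  }
  invisible(x)
}
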