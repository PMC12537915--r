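#' @keywords internal
"_PACKAGE"

# Classed errors: every validation failure carries a specific condition class
# so callers (and the CLI) can map failure kinds to exit codes.
mcdm_abort <- function(message, class) {
  stop(errorCondition(message,
                      class = c(class, "mcdm_error")))
}

abort_validation <- function(message, class = NULL) {
  mcdm_abort(message, c(class, "mcdm_validation_error"))
}

abort_degenerate <- function(message, class = NULL) {
  mcdm_abort(message, c(class, "mcdm_degeneracy_error"))
}

abort_io <- function(message, class = NULL) {
  mcdm_abort(message, c(class, "mcdm_io_error"))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    abort_validation(
      sprintf("`%s` must be a single finite number in [%s, %s], got: %s",
              name, format(lower), format(upper),
              paste(format(x), collapse = ", ")),
      "mcdm_parameter_error")
  }
  invisible(x)
}
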