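# Classed conditions so callers can distinguish bad inputs from bad configs
# and from observations the model cannot explain.

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "benzrisk_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_domain <- function(msg) abort(msg, "benzrisk_domain_error")
abort_config <- function(msg) abort(msg, "benzrisk_config_error")
abort_validation <- function(msg) abort(msg, "benzrisk_validation_error")
abort_saturation <- function(msg, bound = NA_real_) {
  abort(msg, "benzrisk_saturation_error", bound = bound)
}
abort_empty_cohort <- function(msg) abort(msg, "benzrisk_empty_cohort_error")
abort_numeric <- function(msg) abort(msg, "benzrisk_numeric_error")

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_domain(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) abort_domain(sprintf("`%s` must be > 0", name))
  if (nonnegative && x < 0) abort_domain(sprintf("`%s` must be >= 0", name))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
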