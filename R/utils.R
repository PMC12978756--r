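# Input validation helpers. All user-facing errors carry the
# "pulsarch_invalid_input" class so callers (and tests) can catch them.

abort_invalid <- function(msg, ...) {
  rlang::abort(msg, class = "pulsarch_invalid_input", ...)
}

abort_convergence <- function(msg, ...) {
  rlang::abort(msg, class = "pulsarch_convergence_error", ...)
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) || any(!is.finite(x))) {
    abort_invalid(sprintf("`%s` must be finite and numeric.", what))
  }
  invisible(x)
}

check_scalar <- function(x, what) {
  check_finite(x, what)
  if (length(x) != 1) abort_invalid(sprintf("`%s` must be a single number.", what))
  invisible(x)
}

check_positive <- function(x, what) {
  check_finite(x, what)
  if (any(x <= 0)) abort_invalid(sprintf("`%s` must be strictly positive.", what))
  invisible(x)
}

check_non_negative <- function(x, what) {
  check_finite(x, what)
  if (any(x < 0)) abort_invalid(sprintf("`%s` must be non-negative.", what))
  invisible(x)
}

# millimetres of mercury -> pascal, used by the pressure severity bands
mmHg_to_Pa <- function(x) x * 133.322
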