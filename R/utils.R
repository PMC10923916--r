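#' @keywords internal
"_PACKAGE"

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @keywords internal
geomean <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)), all(x > 0))
  exp(mean(log(x)))
}

# INFO-level logging for filtering steps; silenced via option dspmacro.verbose = FALSE.
dsp_log <- function(...) {
  if (isTRUE(getOption("dspmacro.verbose", TRUE))) {
    message("[dspmacro] ", sprintf(...))
  }
  invisible(NULL)
}

dsp_warn <- function(...) warning(sprintf(...), call. = FALSE)

dsp_stop <- function(...) stop(sprintf(...), call. = FALSE)

# Validate a probability vector.
check_probs <- function(p, what = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    dsp_stop("%s must be numeric in [0, 1] with no missing values", what)
  }
  invisible(p)
}
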