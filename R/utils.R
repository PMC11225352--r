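#' @keywords internal
#' @useDynLib silkfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# internal assertion helpers -------------------------------------------------

abort_silkfit <- function(msg, class) {
  stop(structure(
    class = c(class, "silkfit_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_silkfit(sprintf("`%s` must be a single non-missing number", name),
                  "silkfit_validation_error")
  }
  if (x < lower || x > upper) {
    abort_silkfit(sprintf("`%s` = %g outside [%g, %g]", name, x, lower, upper),
                  "silkfit_validation_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# relative difference used by several tests/summaries
rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)
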