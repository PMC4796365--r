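# Classed error conditions so callers can distinguish expected analysis
# failures (no cell in frame, empty masks, ...) from programming errors.

cc_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "constrictr_error"), call = call))
}

#' Check whether a condition object carries a given constrictr error class
#'
#' @param e a condition object (e.g. caught by [tryCatch()]).
#' @param class error class name, e.g. `"NoCellDetected"`.
#' @return `TRUE` or `FALSE`.
#' @export
is_cc_error <- function(e, class) inherits(e, class)

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) cc_stop("NonFiniteInput", sprintf("%s must be finite", what))
}
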