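#' Classed error conditions
#'
#' Every user-facing failure in braidr raises a classed condition so callers
#' (and the test-suite) can discriminate failure modes. The class vector is
#' `c(<specific>, "braidr_error", "error", "condition")`.
#'
#' @param class character scalar, e.g. "spacer_length_error".
#' @param msg message text.
#' @param ... named fields attached to the condition object.
#' @keywords internal
#' @noRd
gb_abort <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "braidr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

gb_warn <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "braidr_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  warning(cond)
}
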