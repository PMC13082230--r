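# Classed conditions so callers can distinguish error kinds programmatically.
abort <- function(message, class) {
  stop(structure(
    class = c(class, "sipraman_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# trapezoidal integral
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

is_uniform_axis <- function(x, tol = 1e-6) {
  d <- diff(x)
  max(d) - min(d) <= tol * stats::median(d)
}

axis_step <- function(x) stats::median(diff(x))

log_msg <- function(...) {
  message(sprintf("[sipraman] %s", sprintf(...)))
}
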