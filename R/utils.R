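# Internal helpers shared across modules.

# Signal a classed condition so callers can distinguish bad files
# (format/parse), bad configuration, bad inputs and per-window
# estimation failures.
abort_respecg <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "respecg_error"),
                      call = call))
}

stop_format <- function(msg) abort_respecg(msg, "respecg_format_error")
stop_config <- function(msg) abort_respecg(msg, "respecg_config_error")
stop_input  <- function(msg) abort_respecg(msg, "respecg_input_error")
stop_io     <- function(msg) abort_respecg(msg, "respecg_io_error")

# Centered moving mean with shrinking windows at the edges, so the
# output has the length of the input and no NA padding. For even n the
# window extends one sample further to the right.
moving_mean <- function(x, n) {
  n <- as.integer(n)
  if (n <= 1L) return(x)
  h1 <- (n - 1L) %/% 2L
  h2 <- n %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_along(x)
  lo <- pmax(i - h1, 1L)
  hi <- pmin(i + h2, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
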