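# Condition classes used across the package. Three families so callers (and
# the command-line dispatcher) can distinguish bad arguments, bad data, and
# I/O problems; each also inherits from "fctarget_error".

stop_arg <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fctarget_arg_error", "fctarget_error", "error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fctarget_data_error", "fctarget_error", "error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fctarget_io_error", "fctarget_error", "error")))
}

check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg("`%s` must be a single finite number", name)
  if (positive && x <= 0)
    stop_arg("`%s` must be positive", name)
  invisible(x)
}
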