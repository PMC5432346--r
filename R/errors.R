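# Condition classes used across the package so callers (and the command-line
# wrapper) can distinguish configuration mistakes, data problems, and
# numerical failures.

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("cvasd_config_error", "cvasd_error")))
}

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("cvasd_validation_error", "cvasd_error")))
}

stop_numeric <- function(msg) {
  stop(errorCondition(msg, class = c("cvasd_numeric_error", "cvasd_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
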