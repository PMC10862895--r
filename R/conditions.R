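# Classed conditions used across the package so callers (and tests) can
# distinguish bad inputs from degenerate data from configuration mistakes.

ss_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "switchscope_error"),
                      call = call))
}

ss_validation_error <- function(field, msg) {
  ss_stop(sprintf("invalid field '%s': %s", field, msg), "ss_validation_error")
}

ss_input_error <- function(msg) ss_stop(msg, "ss_input_error")
ss_no_transition_error <- function(msg) ss_stop(msg, "ss_no_transition_error")
ss_no_signal_error <- function(msg) ss_stop(msg, "ss_no_signal_error")
ss_aggregation_error <- function(msg) ss_stop(msg, "ss_aggregation_error")
ss_config_error <- function(msg) ss_stop(msg, "ss_config_error")
ss_construction_error <- function(msg) ss_stop(msg, "ss_construction_error")
ss_normalization_error <- function(msg) ss_stop(msg, "ss_normalization_error")
ss_merge_error <- function(msg) ss_stop(msg, "ss_merge_error")

stopifnot_scalar_number <- function(x, field, positive = FALSE,
                                    nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ss_validation_error(field, "must be a single finite number")
  if (positive && x <= 0)
    ss_validation_error(field, "must be > 0")
  if (nonnegative && x < 0)
    ss_validation_error(field, "must be >= 0")
  invisible(x)
}
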