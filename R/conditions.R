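# Classed error conditions used across the package so callers/tests can
# distinguish failure modes (format vs domain vs segmentation vs ...).

stop_specfuse <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "specfuse_error"), call = call))
}

abort_domain       <- function(msg) stop_specfuse(msg, "specfuse_domain_error")
abort_format       <- function(msg) stop_specfuse(msg, "specfuse_format_error")
abort_consistency  <- function(msg) stop_specfuse(msg, "specfuse_consistency_error")
abort_io           <- function(msg) stop_specfuse(msg, "specfuse_io_error")
abort_segmentation <- function(msg) stop_specfuse(msg, "specfuse_segmentation_error")
abort_calibration  <- function(msg) stop_specfuse(msg, "specfuse_calibration_error")
abort_spec         <- function(msg) stop_specfuse(msg, "specfuse_spec_error")
abort_split        <- function(msg) stop_specfuse(msg, "specfuse_split_error")
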