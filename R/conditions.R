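# Classed conditions so callers can distinguish failure modes programmatically.
# Every error raised by the package carries class c(paste0("pkd_", class),
# "pkd_error", "error", "condition").

stop_pkd <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("pkd_", class), "pkd_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# classes in use:
#   insufficient_data  - too few quantified points for the requested fit
#   degenerate_model   - Ka == Ke within tolerance (Bateman form undefined)
#   domain             - argument outside its mathematical domain
#   stripping_failed   - curve stripping could not separate the phases
#   singular_design    - zero time variance in a regression
#   alignment          - series do not share a time grid
#   no_crossing        - tolerance bound never falls below the limit
#   config             - inconsistent user configuration
#   validation         - malformed input table
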