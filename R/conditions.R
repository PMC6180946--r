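# Classed conditions so callers can distinguish failure modes programmatically.
# All errors inherit from "emcmed_error"; specific classes are
# "emcmed_<snake_case_name>".

emc_abort <- function(class, msg, call = sys.call(-1), ...) {
  stop(errorCondition(
    msg,
    ...,
    class = c(paste0("emcmed_", class), "emcmed_error"),
    call = call
  ))
}

emc_warn <- function(class, msg, ...) {
  warning(warningCondition(
    msg,
    ...,
    class = c(paste0("emcmed_", class), "emcmed_warning")
  ))
}
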