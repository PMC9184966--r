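# Structured error conditions. Every domain error carries a class name so
# callers (and tests) can dispatch on the failure kind rather than matching
# message text.

lf_stop <- function(class, msg, ...) {
  extra <- list(...)
  cond <- errorCondition(msg, class = c(class, "lf_error"))
  for (nm in names(extra)) cond[[nm]] <- extra[[nm]]
  stop(cond)
}

lf_warn <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "lf_warning")))
}
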