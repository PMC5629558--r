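# Structured conditions. Every domain error carries a class named after the
# failure mode so callers (and tests) can catch it without string matching.

ss_stop <- function(class, message, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "survstrat_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), extra)
  )
  stop(cond)
}

ss_warn <- function(class, message, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "survstrat_warning", "warning", "condition"),
    c(list(message = message, call = sys.call(-1)), extra)
  )
  warning(cond)
}
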