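# Structured condition helpers: every validation failure raises a classed error
# so callers (and the CLI) can distinguish format errors from row-level ones.

gpdrc_error <- function(class, message, data = NULL) {
  structure(
    class = c(class, "gpdrc_error", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
}

stop_gpdrc <- function(class, message, data = NULL) {
  stop(gpdrc_error(class, message, data))
}
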