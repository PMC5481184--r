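# Classed error conditions so callers can distinguish failure modes.

phreno_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "phrenoscope_error", "error")))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    phreno_stop("InvalidParams", "`%s` must be a single finite number", name)
  if (positive && x <= 0)
    phreno_stop("InvalidParams", "`%s` must be > 0", name)
  invisible(x)
}
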