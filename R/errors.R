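# Classed conditions so callers (and the pipeline's drop log) can dispatch on
# the error family rather than match message text.
abort_sb <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "swayboard_error")))
}

stopifnot_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_sb(sprintf("`%s` must be a single finite number", name),
             "swayboard_parameter_error")
  if (positive && x <= 0)
    abort_sb(sprintf("`%s` must be > 0", name), "swayboard_parameter_error")
  invisible(x)
}
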