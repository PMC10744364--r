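# Internal helpers: condition constructors and small validators.

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ftdqeeg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    abort(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper),
          "validation_error")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
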