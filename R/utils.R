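# internal helpers shared across modules

# stop with a classed condition so tests can assert on error class
vt_abort <- function(msg, class = "vasotherm_error") {
  rlang::abort(msg, class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    vt_abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    vt_abort(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

check_strictly_increasing <- function(x, name) {
  if (length(x) > 1L && any(diff(x) <= 0)) {
    vt_abort(sprintf("`%s` must be strictly increasing.", name))
  }
  invisible(x)
}

# derive a stream of child seeds from one integer seed, all below 2^31
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
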