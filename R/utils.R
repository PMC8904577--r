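# Internal argument checks. All user-facing errors are classed so the CLI can
# render them as one-line diagnostics.

abort_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("pgsabs_domain_error", "error")))
}

check_prob_open <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1)
    abort_domain("`%s` must be a single number strictly between 0 and 1 (got %s)",
                 name, format(x))
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    abort_domain("`%s` must be a single non-negative number (got %s)", name, format(x))
  invisible(x)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_domain("`%s` must be a single finite number (got %s)", name, format(x))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    abort_domain("`%s` must be an integer >= %d (got %s)", name, min, format(x))
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
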