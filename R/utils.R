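# internal argument checks; every public op funnels through these so that
# error messages always name the offending field and its unit

check_number <- function(x, name, unit = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number%s", name,
                 if (is.null(unit)) "" else paste0(" (", unit, ")")),
         call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name, unit = NULL) {
  check_number(x, name, unit)
  if (x <= 0) {
    stop(sprintf("`%s` must be strictly positive%s, got %g", name,
                 if (is.null(unit)) "" else paste0(" (", unit, ")"), x),
         call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x, name, unit = NULL) {
  check_number(x, name, unit)
  if (x < 0) {
    stop(sprintf("`%s` must be non-negative, got %g", name, x), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name) {
  check_number(x, name)
  if (x < 1 || x != round(x)) {
    stop(sprintf("`%s` must be a positive integer, got %g", name, x),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# relative agreement helper used by constructors that accept redundant inputs
rel_diff <- function(x, ref) abs(x - ref) / abs(ref)
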