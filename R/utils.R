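# internal validation helpers

stop_field <- function(field, msg) {
  stop(sprintf("invalid scenario field `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lo = -Inf, hi = Inf,
                         strict_lo = FALSE, strict_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  ok_lo <- if (strict_lo) x > lo else x >= lo
  ok_hi <- if (strict_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi)
    stop_field(field, sprintf("value %g outside [%g, %g]", x, lo, hi))
  invisible(x)
}

check_fraction <- function(x, field) check_number(x, field, 0, 1)

check_names <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
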