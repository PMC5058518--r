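# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# scalar checks used by the config/argument validators
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%s, %s]", name, lower, upper)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stopf("`%s` must be a whole number", name)
  invisible(as.integer(x))
}

check_prob <- function(x, name) check_number(x, name, 0, 1)

# require columns in a data frame
check_columns <- function(df, cols, name) {
  if (!is.data.frame(df)) stopf("`%s` must be a data frame", name)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("`%s` is missing column(s): %s", name, paste(miss, collapse = ", "))
  invisible(df)
}

# Dates covering an inclusive window; error listing the gaps (no imputation)
check_window_coverage <- function(dates, from, to, what) {
  expected <- seq(from, to, by = "day")
  missing <- expected[!expected %in% dates]
  if (length(missing)) {
    shown <- paste(format(head(missing, 10L)), collapse = ", ")
    more <- if (length(missing) > 10L)
      sprintf(" (and %d more)", length(missing) - 10L) else ""
    stopf("%s: %d missing day(s) in %s..%s: %s%s",
          what, length(missing), format(from), format(to), shown, more)
  }
  invisible(expected)
}
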