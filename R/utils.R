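# Internal helpers shared across modules.

# Fraction comparison with a small absolute tolerance so that exact rational
# boundaries (e.g. 850/1000 vs 0.85, 2550/3000 vs 0.85) are classified
# inclusively regardless of binary rounding. num and den are integers in
# practice, so true differences are never smaller than 1/den >> 1e-9.
frac_ge <- function(num, den, threshold) {
  num / den >= threshold - 1e-9
}

# Total length of the union of 1-based inclusive intervals.
# starts/ends: integer vectors of equal length; intervals may overlap.
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]
  ends <- ends[o]
  total <- 0L
  cur_start <- starts[1L]
  cur_end <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur_end + 1L) {
      if (ends[i] > cur_end) cur_end <- ends[i]
    } else {
      total <- total + (cur_end - cur_start + 1L)
      cur_start <- starts[i]
      cur_end <- ends[i]
    }
  }
  total + (cur_end - cur_start + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
msgf <- function(fmt, ...) message(sprintf(fmt, ...))

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L)
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}
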