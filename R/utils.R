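# Internal helpers shared across modules.

# Canonical text rendering of a p-value threshold, used to key the
# `targets_at` columns of eQTL summaries. Both writers and readers of the
# key must go through this function.
fmt_threshold <- function(x) {
  trimws(formatC(x, format = "g", digits = 15))
}

# Derive independent per-replicate seeds from one user seed so replicate i is
# reproducible regardless of execution order. Seeds stay below 2^31.
substream_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# sample() treats a length-one numeric x as 1:x; this version never does.
sample_vec <- function(x, size) {
  if (length(x) == 1L && size == 1L) return(x)
  sample(x, size)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "eqtlenrich_schema_error")
  }
  invisible(df)
}
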