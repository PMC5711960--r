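`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf-style formatting and no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# empty data.frame with the given column prototypes
empty_df <- function(proto) {
  as.data.frame(lapply(proto, function(x) x[0]), stringsAsFactors = FALSE)
}

#' @noRd
assert_columns <- function(df, cols, where = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort("%s is missing mandatory column(s): %s", where,
          paste(missing, collapse = ", "))
  }
  invisible(df)
}

# run expr under a fixed RNG state without touching the caller's stream;
# seed = NULL leaves the global stream in place (and advances it)
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
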