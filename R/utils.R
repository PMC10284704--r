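# Internal helpers: seeded evaluation and argument checks.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards.  All generator functions route their randomness through this so
# that no call leaves global state behind.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

check_positive_scalar <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop(sprintf("`%s` must be a %s finite number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  invisible(x)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s (found: %s)",
                 what, paste(missing, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
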