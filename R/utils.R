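# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed for the (condition index, scenario) stream.
# Keyed by condition *position* so appending a condition leaves earlier
# streams untouched; kept below 2^31.
derive_stream_seed <- function(seed, cond_index, scenario) {
  as.integer((as.numeric(seed) + 1000003 * cond_index + 7919 * scenario) %%
               2147483629)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Collect validation messages; stop once listing every violation.
fail_validation <- function(problems, what) {
  stop(sprintf("invalid %s:\n%s", what,
               paste0("  - ", problems, collapse = "\n")), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
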