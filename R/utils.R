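# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed for sub-computation `k`, kept inside 32-bit range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 1009L * as.integer(k)) %% 2147483647L
}

stop_dim <- function(found, expected, what = "columns") {
  stop(sprintf("dimension mismatch: %d %s supplied, model expects %d",
               found, what, expected), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
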