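# Internal helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never disturbs user
# randomness.
with_local_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic per-stage seed derived from a single pipeline seed; kept
# well inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(synthetic = 101L, folds = 211L, outliers = 307L,
               taa = 401L, tfc = 409L)
  if (!stage %in% names(offsets)) {
    stop("unknown seed stage: ", stage, call. = FALSE)
  }
  (as.integer(seed) %% 1000000000L) + offsets[[stage]]
}
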