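# Internal helpers: seeded evaluation and substream derivation.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Derive a reproducible substream seed (< 2^31 - 1) from a master seed and
# a stream name, so pipeline stages can be regenerated independently.
# Polynomial rolling hash: low collision risk even for near-identical
# stream names.
deriveSeed <- function(masterSeed, stream) {
  h <- abs(masterSeed) %% 2147483647
  for (code in utf8ToInt(stream)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Lightweight condition-free logging used across the pipeline.
logMsg <- function(...) {
  message("[netmodule] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
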