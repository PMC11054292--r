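#' Deterministic substream seeds
#'
#' All stochastic operations in the package draw from named substreams of a
#' single root seed, so any individual scene, patch or training run can be
#' regenerated in isolation.  The substream seed is a 31-bit hash of the root
#' seed and the stream name.
#'
#' @param root integer root seed.
#' @param name character scalar naming the substream (e.g. `"scene/12"`).
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
substream_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1, is.character(name))
  h <- abs(as.numeric(root)) %% 2147483647
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer(max(1, h))
}

# Uniform integer in [lo, hi], safe when lo == hi (unlike sample(x, 1)).
sample_int_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
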