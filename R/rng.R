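# Deterministic sub-seed derivation: one root seed, named substreams.
# Tree generation, branch lengths and baselines each draw from their own
# substream so that adding a consumer never perturbs the others.

#' Derive a reproducible sub-seed from a root seed and a label
#'
#' @param seed integer root seed.
#' @param label character tag of the substream.
#' @return an integer in `[0, 2^31 - 2]`, deterministic in `(seed, label)`.
#' @export
derive_seed <- function(seed, label) {
  m <- 2147483647  # 2^31 - 1 (prime)
  h <- as.double(seed %% m)
  for (c in utf8ToInt(as.character(label)))
    h <- (h * 69069 + c) %% m
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, label).
.with_seed <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, label))
  expr
}
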