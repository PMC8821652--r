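#' Derive a reproducible sub-stream seed
#'
#' All stochastic operations in the package draw their randomness from a
#' sub-seed derived deterministically from one global seed and a short key
#' naming the operation, so that changing one stage of a pipeline never
#' perturbs the random stream of another.
#'
#' @param seed Integer global seed.
#' @param key Character scalar naming the consumer (e.g. `"trial"`, `"ci"`).
#' @return An integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "trial")
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((abs(seed) * 69069 + h * 7919) %% (2^31 - 1))
}

# Evaluate `expr` under a local RNG state seeded from (seed, key); the
# caller's RNG state is untouched.
with_subseed <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, key))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
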