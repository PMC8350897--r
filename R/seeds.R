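#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from a single master seed. Independent
#' random streams (one per sample, per locus table, per CV repeat, ...) get
#' their own seed derived deterministically from the master seed and a string
#' key, so that adding or reordering one stream never perturbs another.
#'
#' The hash is a plain polynomial rolling hash over the UTF-8 bytes of the key,
#' carried out in double precision below 2^31 so the result is identical on
#' every platform and always a valid R integer seed.
#'
#' @param master_seed integer master seed.
#' @param key character scalar naming the stream (e.g. "sample/12").
#' @return an integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, key) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(key), length(key) == 1L)
  mod <- 2147483647   # 2^31 - 1, prime
  h <- as.double(master_seed) %% mod
  for (b in as.integer(charToRaw(key))) {
    h <- (h * 31 + b) %% mod
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
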