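#' Derive a deterministic sub-seed from a global seed and a stage label
#'
#' All generators in the package draw their randomness from a single global
#' seed. Each stage (genome, fragments, images, Ct tables, ...) derives its
#' own sub-seed from `(seed, label)` so that stages can be re-run
#' independently and in any order without perturbing one another.
#'
#' The derivation hashes the label bytes with a Horner scheme modulo
#' 2^31 - 1 and mixes in the seed by multiplication with a fixed odd
#' constant; the result is always a strictly positive 31-bit integer.
#'
#' @param seed integer global seed.
#' @param label character scalar naming the stage (e.g. `"fragments"`).
#' @return a positive integer < 2^31, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "fragments")
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% m
  # 48271 is the MINSTD multiplier; products stay far below 2^53
  s <- (abs(as.numeric(seed)) %% m) * 48271 %% m
  out <- (h * 69621 + s + 1) %% m
  as.integer(out + 1)
}

# Run code under a temporary RNG state restored on exit.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
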