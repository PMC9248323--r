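#' Derive a named substream seed from a root seed
#'
#' All random draws in the package flow from a single root seed via named
#' substreams: each generator hashes its own name together with the root
#' seed, so adding a new generator never perturbs the draws of existing
#' ones.
#'
#' @param seed integer root seed.
#' @param name character scalar naming the substream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(name)) {
    # multiplier small enough that h * 69069 + code stays below 2^53
    h <- (h * 69069 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate code under a named substream of a root seed
#'
#' Restores the caller's RNG state afterwards.
#'
#' @param seed integer root seed.
#' @param name substream name.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}
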