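#' Derive a named substream seed from a master seed
#'
#' All stochastic stages (cohort synthesis, model initialisation, warm-phase
#' sampling, slide visit order, buffer shuffling, augmentation, bootstrap
#' resampling) draw their seeds from one master seed through named
#' substreams, so that stages are individually reproducible and do not
#' consume each other's random numbers.
#'
#' @param master integer master seed.
#' @param name substream name, e.g. `"visit-order"`; distinct names give
#'   (with overwhelming probability) distinct streams.
#' @param index optional integer index for per-epoch / per-slide substreams.
#' @return an integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' substream_seed(42, "visit-order", 3)
substream_seed <- function(master, name, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name),
            length(index) == 1L)
  h <- 0
  for (u in utf8ToInt(name)) h <- (h * 131 + u) %% 1000003
  .mix_seed(master, h, index)
}

# small multiplicative mix; kept below 2^31 - 1 at every step
.mix_seed <- function(master, h, index) {
  m <- abs(as.numeric(master)) %% 2147483647
  x <- (m * 2654435 + h * 40503 + as.numeric(index) * 69069 + 12345) %% 2147483647
  as.integer(x)
}

#' Evaluate code with a temporary RNG seed
#'
#' Wrapper around [withr::with_seed()] pinned to the Mersenne-Twister
#' generator so results do not depend on the session's RNG kind.
#'
#' @param seed integer seed.
#' @param code code to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}
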