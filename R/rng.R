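#' Derive a deterministic substream seed from a master seed
#'
#' Every stochastic operation in the simulator draws from its own named
#' substream so that, e.g., adding a reader or editing the growth model never
#' perturbs cohort generation. The substream seed is a deterministic mix of
#' the master seed and the stream name.
#'
#' @param master_seed Integer master seed for the whole run.
#' @param stream Character stream name, e.g. `"cohort"`, `"reader/R3"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1L, "cohort")
substream_seed <- function(master_seed, stream) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stream), length(stream) == 1L)
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 31 + code) %% 2147483647
  as.integer((abs(master_seed) + h) %% 2147483646) + 1L
}

# Evaluate `code` under the named substream, restoring the caller's RNG state.
with_substream <- function(master_seed, stream, code) {
  withr::with_seed(substream_seed(master_seed, stream), code)
}
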