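#' Default reader measurement profiles
#'
#' Each reader is a measurement process characterized by an additive bias
#' (mm), a Gaussian noise SD (mm) and whether the reported value is rounded
#' to whole millimetres:
#'
#' * `R0` true size (reference; exact, unrounded),
#' * `R1` consensus of radiologists (bias 0, SD 0.1),
#' * `R2` AI alone (bias +0.234, SD 0.771),
#' * `R3` AI-assisted radiologist (bias +0.182, SD 0.639),
#' * `R4` unassisted radiologist, manual calipers (bias -0.770, SD 0.959).
#'
#' @param zero_bias If `TRUE`, set all biases to 0 while keeping each
#'   reader's SD (the "bias removed" scenario).
#' @return A data frame with columns `reader_id`, `label`, `bias_mm`,
#'   `sd_mm`, `rounds_to_mm`.
#' @export
#' @examples
#' reader_defaults()
reader_defaults <- function(zero_bias = FALSE) {
  r <- data.frame(
    reader_id = c("R0", "R1", "R2", "R3", "R4"),
    label = c("True size", "Radiologist consensus", "AI alone",
              "AI-assisted radiologist", "Unassisted radiologist"),
    bias_mm = c(0, 0, 0.234, 0.182, -0.770),
    sd_mm = c(0, 0.1, 0.771, 0.639, 0.959),
    rounds_to_mm = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  if (zero_bias) r$bias_mm <- 0
  r
}

round_half_up <- function(x) floor(x + 0.5)

#' Simulate one reader's measurement of true diameters
#'
#' Adds the reader's bias and Gaussian noise, optionally rounds half-up to
#' whole millimetres, and clamps at 1 mm. Noise is independent across
#' scans and across readers.
#'
#' @param true_d True diameter(s), mm (> 0).
#' @param reader One row of [reader_defaults()] (or a list with the same
#'   fields).
#' @param noise Optional pre-generated noise vector (one `N(0, sd^2)` draw
#'   per element of `true_d`); drawn internally when omitted.
#' @return Measured diameter(s), mm; integers for rounding readers.
#' @export
#' @examples
#' measure(6.5, list(bias_mm = 0, sd_mm = 0, rounds_to_mm = TRUE))  # 7
measure <- function(true_d, reader, noise = NULL) {
  if (any(true_d <= 0)) stop("true_d must be > 0")
  if (is.null(noise)) {
    noise <- if (reader$sd_mm > 0) stats::rnorm(length(true_d), 0, reader$sd_mm)
             else numeric(length(true_d))
  }
  raw <- true_d + reader$bias_mm + noise
  if (isTRUE(reader$rounds_to_mm)) raw <- round_half_up(raw)
  pmax(raw, 1)
}

#' Pre-generate a reader's random draws for a cohort
#'
#' Generates the per-scan measurement noise and the baseline referral
#' uniforms from the reader's own substream, so that adding or removing a
#' reader never perturbs another reader's outcomes, and so that the
#' vectorized engine and the per-nodule reference engine consume exactly
#' the same randomness.
#'
#' @param n Number of nodules.
#' @param reader One row of [reader_defaults()].
#' @param seed Master seed; uses the `"reader/<id>"` substream.
#' @param times Scan times (months) for which noise columns are generated.
#' @return A list with `times`, an `n x length(times)` noise matrix, and a
#'   length-`n` vector `referral` of uniforms.
#' @export
reader_draws <- function(n, reader, seed, times = c(0, 3, 12, 24, 48)) {
  with_substream(seed, paste0("reader/", reader$reader_id), {
    noise <- if (reader$sd_mm > 0) {
      matrix(stats::rnorm(n * length(times), 0, reader$sd_mm), nrow = n)
    } else {
      matrix(0, nrow = n, ncol = length(times))
    }
    referral <- stats::runif(n)
  })
  colnames(noise) <- as.character(times)
  list(times = times, noise = noise, referral = referral)
}
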