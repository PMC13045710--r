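#' Shifted, truncated log-normal diameter distribution
#'
#' Baseline nodule diameters are modelled as `shift + X` where
#' `log X ~ N(meanlog, sdlog^2)`, with values above `max_diameter`
#' rejected. The shift (3 mm here) reflects the lower bound of the
#' nodule definition; the truncation bound (30 mm) is the upper bound
#' beyond which a lesion is a mass, not a nodule.
#'
#' @param meanlog Mean of the log of the unshifted variable.
#' @param sdlog Standard deviation of the log of the unshifted variable.
#' @param shift Additive offset in mm (default 0).
#' @param max_diameter Truncation bound in mm on the shifted scale
#'   (default `Inf`, i.e. untruncated).
#' @return An object of class `"lognormal_spec"`.
#' @export
#' @examples
#' lognormal_spec(-0.51, 1.97^2, shift = 3, max_diameter = 30)
lognormal_spec <- function(meanlog, sdlog, shift = 0, max_diameter = Inf) {
  stopifnot(is.numeric(meanlog), is.numeric(sdlog), is.numeric(shift),
            is.numeric(max_diameter))
  if (sdlog <= 0) stop("sdlog must be > 0")
  if (shift < 0) stop("shift must be >= 0")
  if (max_diameter <= shift) stop("max_diameter must exceed shift")
  structure(list(meanlog = meanlog, sdlog = sdlog, shift = shift,
                 max_diameter = max_diameter),
            class = "lognormal_spec")
}

# Inverse error function via the normal quantile: erfinv(x) = qnorm((1+x)/2)/sqrt(2)
erf_inv <- function(x) stats::qnorm((1 + x) / 2) / sqrt(2)

#' Quantile of the shifted (untruncated) log-normal
#'
#' Computes `shift + exp(meanlog + sqrt(2) * sdlog * erfinv(2p - 1))`, the
#' quantile function of the shifted log-normal, used both to parameterize
#' the diameter model from published median/IQR summaries and as the basis
#' of [solve_sdlog()].
#'
#' @param p Probability in (0, 1); vectorized.
#' @param spec A [lognormal_spec()].
#' @return Quantile(s) in mm (truncation is ignored here).
#' @export
#' @examples
#' # median of a part-solid nodule diameter model
#' lognormal_quantile(0.5, lognormal_spec(2.19, 0.87, shift = 3))
lognormal_quantile <- function(p, spec) {
  stopifnot(inherits(spec, "lognormal_spec"))
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly within (0, 1)")
  spec$shift + exp(spec$meanlog + sqrt(2) * spec$sdlog * erf_inv(2 * p - 1))
}

#' Solve for the log-scale SD from a published median and IQR
#'
#' Given the median and interquartile range of a shifted log-normal,
#' sets `meanlog = log(median - shift)` and solves for the `sdlog` whose
#' 0.75 and 0.25 quantiles differ by `iqr`, by bisection.
#'
#' @param median Median of the shifted variable, in mm.
#' @param iqr Interquartile range in mm.
#' @param shift Additive offset in mm.
#' @param interval Search interval for `sdlog`.
#' @param tol Absolute tolerance on the IQR mismatch.
#' @return A list with elements `meanlog` and `sdlog`.
#' @export
#' @examples
#' solve_sdlog(11.9, 11.1, shift = 3)  # sdlog approximately 0.87
solve_sdlog <- function(median, iqr, shift = 0, interval = c(1e-6, 20),
                        tol = 1e-9) {
  if (median <= shift) stop("median must exceed shift")
  if (iqr <= 0) stop("iqr must be > 0")
  meanlog <- log(median - shift)
  z75 <- stats::qnorm(0.75)
  gap <- function(s) {
    exp(meanlog + s * z75) - exp(meanlog - s * z75) - iqr
  }
  if (gap(interval[1]) > 0 || gap(interval[2]) < 0)
    stop("no sdlog in the search interval reproduces this IQR")
  lo <- interval[1]; hi <- interval[2]
  while (TRUE) {
    mid <- (lo + hi) / 2
    g <- gap(mid)
    if (abs(g) < tol || (hi - lo) < 1e-14) break
    if (g < 0) lo <- mid else hi <- mid
  }
  list(meanlog = meanlog, sdlog = mid)
}

#' CDF of the shifted truncated log-normal
#'
#' Analytic distribution function of the diameter model, used as the
#' reference distribution in goodness-of-fit checks of sampled cohorts.
#'
#' @param q Quantiles in mm (shifted scale); vectorized.
#' @param spec A [lognormal_spec()].
#' @return `P(D <= q)` under truncation at `max_diameter`.
#' @export
ptrunc_shifted_lognormal <- function(q, spec) {
  stopifnot(inherits(spec, "lognormal_spec"))
  denom <- stats::plnorm(spec$max_diameter - spec$shift,
                         spec$meanlog, spec$sdlog)
  p <- stats::plnorm(pmin(q, spec$max_diameter) - spec$shift,
                     spec$meanlog, spec$sdlog) / denom
  p[q <= spec$shift] <- 0
  p
}

#' Mean of the shifted truncated log-normal
#'
#' Closed form: `shift + exp(mu + s^2/2) * pnorm((log(M - shift) - mu - s^2)/s)
#' / pnorm((log(M - shift) - mu)/s)` where `M` is the truncation bound.
#' Serves as the analytic oracle for sampled cohort means.
#'
#' @param spec A [lognormal_spec()].
#' @return The mean diameter in mm.
#' @export
mean_trunc_shifted_lognormal <- function(spec) {
  stopifnot(inherits(spec, "lognormal_spec"))
  m <- spec$meanlog; s <- spec$sdlog
  lm <- log(spec$max_diameter - spec$shift)
  spec$shift + exp(m + s^2 / 2) *
    stats::pnorm((lm - m - s^2) / s) / stats::pnorm((lm - m) / s)
}
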