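#' Nodule subtype mixture
#'
#' A cohort is a mixture of solid, part-solid and non-solid (ground-glass)
#' nodules, each with its own diameter distribution. Part-solid and
#' non-solid together form the "sub-solid" class.
#'
#' @param weights Named numeric vector of probabilities for
#'   `solid`, `part_solid` and `non_solid`; must sum to 1 (within 1e-12).
#' @param specs Named list of [lognormal_spec()] objects, one per subtype.
#' @return An object of class `"subtype_mixture"`.
#' @export
subtype_mixture <- function(weights, specs) {
  nm <- c("solid", "part_solid", "non_solid")
  stopifnot(setequal(names(weights), nm), setequal(names(specs), nm))
  weights <- weights[nm]; specs <- specs[nm]
  if (abs(sum(weights) - 1) > 1e-12) stop("subtype weights must sum to 1")
  if (any(weights < 0)) stop("subtype weights must be non-negative")
  for (s in specs) stopifnot(inherits(s, "lognormal_spec"))
  structure(list(weights = weights, specs = specs), class = "subtype_mixture")
}

#' Default subtype mixture for a screening population
#'
#' 93.9% solid; the remaining 6.1% sub-solid split part-solid : non-solid
#' = 4 : 5. Diameter models (mm): solid `3 + LN(-0.51, 1.97^2)`,
#' part-solid `3 + LN(2.19, 0.87^2)`, non-solid `3 + LN(1.03, 1.13^2)`,
#' all truncated at 30 mm. The log-scale SDs are the squares of the printed
#' base values; with these the truncated-distribution medians and means of
#' the sampled cohort match the published summaries.
#'
#' @param solid_fraction Proportion of solid nodules.
#' @param part_non_ratio Length-2 ratio of part-solid to non-solid within
#'   the sub-solid fraction.
#' @return A [subtype_mixture()].
#' @export
default_subtype_mixture <- function(solid_fraction = 0.939,
                                    part_non_ratio = c(4, 5)) {
  sub <- 1 - solid_fraction
  r <- part_non_ratio / sum(part_non_ratio)
  subtype_mixture(
    weights = c(solid = solid_fraction,
                part_solid = sub * r[1],
                non_solid = sub * r[2]),
    specs = list(
      solid = lognormal_spec(-0.51, 1.97^2, shift = 3, max_diameter = 30),
      part_solid = lognormal_spec(2.19, 0.87^2, shift = 3, max_diameter = 30),
      non_solid = lognormal_spec(1.03, 1.13^2, shift = 3, max_diameter = 30)
    )
  )
}

#' Size-band malignancy prevalence
#'
#' Probability that a nodule is malignant, by nodule class and baseline
#' true diameter band. Bands are half-open `[lower, upper)` except the
#' final band of each class, which is closed above.
#'
#' @return A list with elements `solid` and `sub_solid`, each a data frame
#'   with columns `lower`, `upper`, `prob`.
#' @export
default_prevalence_bands <- function() {
  list(
    solid = data.frame(lower = c(3, 6, 8), upper = c(6, 8, 30),
                       prob = c(0.009, 0.011, 0.094)),
    sub_solid = data.frame(lower = c(3, 5), upper = c(5, 30),
                           prob = c(0.004, 0.036))
  )
}

validate_bands <- function(bands) {
  for (cls in c("solid", "sub_solid")) {
    b <- bands[[cls]]
    stopifnot(is.data.frame(b), all(c("lower", "upper", "prob") %in% names(b)))
    if (any(b$prob < 0 | b$prob > 1)) stop("band probabilities must be in [0,1]")
    if (nrow(b) > 1 && any(b$lower[-1] != b$upper[-nrow(b)]))
      stop("bands must be contiguous for class ", cls)
  }
  invisible(bands)
}

# Band probability lookup on true diameter for one class.
band_prob <- function(d, band) {
  if (any(d < band$lower[1] | d > band$upper[nrow(band)]))
    stop("diameter outside configured prevalence bands")
  band$prob[findInterval(d, band$lower)]
}

is_subsolid <- function(subtype) subtype %in% c("part_solid", "non_solid")

# Rejection sampler for one shifted truncated log-normal.
sample_trunc_lognormal <- function(n, spec) {
  x <- spec$shift + stats::rlnorm(n, spec$meanlog, spec$sdlog)
  bad <- which(x > spec$max_diameter)
  while (length(bad)) {
    x[bad] <- spec$shift + stats::rlnorm(length(bad), spec$meanlog, spec$sdlog)
    bad <- bad[x[bad] > spec$max_diameter]
  }
  x
}

#' Sample a baseline cohort of risk-dominant nodules
#'
#' Draws subtypes from the mixture weights and baseline true diameters from
#' each subtype's shifted log-normal, rejecting and redrawing values above
#' the truncation bound so that exactly `n` nodules are returned, all with
#' diameters in `(shift, max_diameter]`.
#'
#' @param n Number of nodules (one per person).
#' @param mixture A [subtype_mixture()].
#' @param seed Master seed; the draws use the `"cohort"` substream.
#' @return A data frame with columns `id`, `subtype` (factor), `true_d0`
#'   (mm, unrounded) and placeholder columns `malignant`, `benign_features`.
#' @export
#' @examples
#' head(sample_cohort(100, seed = 1))
sample_cohort <- function(n, mixture = default_subtype_mixture(), seed = 1) {
  stopifnot(n > 0, inherits(mixture, "subtype_mixture"))
  lv <- names(mixture$weights)
  with_substream(seed, "cohort", {
    subtype <- sample(lv, n, replace = TRUE, prob = mixture$weights)
    d <- numeric(n)
    for (st in lv) {
      idx <- which(subtype == st)
      if (length(idx)) d[idx] <- sample_trunc_lognormal(length(idx),
                                                        mixture$specs[[st]])
    }
  })
  data.frame(id = seq_len(n),
             subtype = factor(subtype, levels = lv),
             true_d0 = d,
             malignant = NA,
             benign_features = NA)
}

#' Assign malignancy flags by size band
#'
#' Independent Bernoulli draw per nodule with the prevalence of its class
#' (solid vs sub-solid) and true-diameter band.
#'
#' @param cohort Output of [sample_cohort()].
#' @param bands As returned by [default_prevalence_bands()].
#' @param seed Master seed; uses the `"malignancy"` substream.
#' @return The cohort with the `malignant` column filled.
#' @export
assign_malignancy <- function(cohort, bands = default_prevalence_bands(),
                              seed = 1) {
  validate_bands(bands)
  sub <- is_subsolid(cohort$subtype)
  p <- numeric(nrow(cohort))
  if (any(!sub)) p[!sub] <- band_prob(cohort$true_d0[!sub], bands$solid)
  if (any(sub)) p[sub] <- band_prob(cohort$true_d0[sub], bands$sub_solid)
  u <- with_substream(seed, "malignancy", stats::runif(nrow(cohort)))
  cohort$malignant <- u < p
  cohort
}

#' Assign benign-feature flags
#'
#' A fraction of non-malignant nodules at least `min_diameter` mm (true
#' size) show clearly benign imaging features (e.g. calcification) and are
#' discharged immediately at baseline. Malignant nodules are never flagged.
#'
#' @param cohort Cohort with malignancy already assigned.
#' @param rate Flag probability among eligible benign nodules (default 0.10).
#' @param min_diameter Eligibility threshold in mm (default 5).
#' @param seed Master seed; uses the `"features"` substream.
#' @return The cohort with the `benign_features` column filled.
#' @export
assign_benign_features <- function(cohort, rate = 0.10, min_diameter = 5,
                                   seed = 1) {
  if (anyNA(cohort$malignant)) stop("assign malignancy before benign features")
  stopifnot(rate >= 0, rate <= 1)
  u <- with_substream(seed, "features", stats::runif(nrow(cohort)))
  cohort$benign_features <-
    !cohort$malignant & cohort$true_d0 >= min_diameter & u < rate
  cohort
}
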