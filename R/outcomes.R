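#' Disposition-by-timepoint table
#'
#' Cross-tabulates final dispositions by reader, truth class (malignant /
#' benign) and timepoint: how many nodules were referred for definitive
#' management (DM) or discharged (DC) at each scan, how many continued to
#' the next scan, and the cumulative percentages of the class total.
#'
#' @param outcomes Output of [run_population()].
#' @param cohort The cohort the outcomes were simulated from.
#' @param timepoints Scan times (months) to tabulate.
#' @return A data frame with columns `reader_id`, `truth`, `timepoint`,
#'   `n_dm`, `n_dc`, `n_continuing`, `cum_dm_pct`, `cum_dc_pct`.
#' @export
timepoint_table <- function(outcomes, cohort,
                            timepoints = c(0, 3, 12, 24, 48)) {
  if (nrow(outcomes) &&
      (anyNA(outcomes$disposition) ||
       !all(outcomes$disposition %in% c("DM", "DC"))))
    stop("outcomes contain missing or unknown dispositions")
  truth <- ifelse(cohort$malignant[match(outcomes$nodule_id, cohort$id)],
                  "malignant", "benign")
  res <- list()
  for (r in unique(outcomes$reader_id)) {
    for (cls in c("malignant", "benign")) {
      sel <- outcomes$reader_id == r & truth == cls
      n_cls <- sum(sel)
      dt <- outcomes$decision_time[sel]
      dp <- outcomes$disposition[sel]
      for (tp in timepoints) {
        n_dm <- sum(dp == "DM" & dt == tp)
        n_dc <- sum(dp == "DC" & dt == tp)
        res[[length(res) + 1L]] <- data.frame(
          reader_id = r, truth = cls, timepoint = tp,
          n_dm = n_dm, n_dc = n_dc,
          n_continuing = sum(dt > tp),
          cum_dm_pct = if (n_cls) 100 * sum(dp == "DM" & dt <= tp) / n_cls else 0,
          cum_dc_pct = if (n_cls) 100 * sum(dp == "DC" & dt <= tp) / n_cls else 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res))
    return(data.frame(reader_id = character(), truth = character(),
                      timepoint = numeric(), n_dm = numeric(),
                      n_dc = numeric(), n_continuing = numeric(),
                      cum_dm_pct = numeric(), cum_dc_pct = numeric()))
  do.call(rbind, res)
}

#' Sensitivity, specificity and surveillance-time summary
#'
#' Per reader and population (combined, solid, sub-solid): sensitivity is
#' the fraction of malignant nodules referred for definitive management by
#' the end of follow-up; specificity the fraction of benign nodules
#' discharged; surveillance time is the mean (SD) of the decision time in
#' months over all nodules of the population (0 for baseline decisions).
#'
#' @param outcomes Output of [run_population()].
#' @param cohort The cohort the outcomes were simulated from.
#' @return A data frame with one row per reader x population.
#' @export
accuracy_summary <- function(outcomes, cohort) {
  pos <- match(outcomes$nodule_id, cohort$id)
  mal <- cohort$malignant[pos]
  sub <- is_subsolid(cohort$subtype[pos])
  pops <- list(combined = rep(TRUE, nrow(outcomes)),
               solid = !sub, sub_solid = sub)
  res <- list()
  for (r in unique(outcomes$reader_id)) {
    for (p in names(pops)) {
      sel <- outcomes$reader_id == r & pops[[p]]
      m <- mal[sel]
      dm <- outcomes$disposition[sel] == "DM"
      dt <- outcomes$decision_time[sel]
      res[[length(res) + 1L]] <- data.frame(
        reader_id = r, population = p,
        n_malignant = sum(m), n_benign = sum(!m),
        sensitivity = if (any(m)) mean(dm[m]) else NA_real_,
        specificity = if (any(!m)) mean(!dm[!m]) else NA_real_,
        mean_surveillance = mean(dt),
        sd_surveillance = stats::sd(dt),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Pairwise reader comparison with Monte-Carlo standard errors
#'
#' Tabulates differences in sensitivity, specificity and mean surveillance
#' time between each reader and a reference reader, with binomial /
#' large-sample Monte-Carlo standard errors for the differences.
#'
#' @param summary Output of [accuracy_summary()].
#' @param reference Reader id to compare against (default `"R4"`).
#' @param population Population to compare on (default `"combined"`).
#' @return A data frame of differences (`reader - reference`) and their
#'   standard errors.
#' @export
compare_readers <- function(summary, reference = "R4",
                            population = "combined") {
  s <- summary[summary$population == population, , drop = FALSE]
  if (nrow(s) < 2) stop("need at least two readers to compare")
  if (!reference %in% s$reader_id) stop("reference reader not in summary")
  ref <- s[s$reader_id == reference, ]
  oth <- s[s$reader_id != reference, , drop = FALSE]
  se_p <- function(p, n) sqrt(p * (1 - p) / n)
  data.frame(
    reader_id = oth$reader_id,
    reference = reference,
    d_sensitivity = oth$sensitivity - ref$sensitivity,
    se_sensitivity = sqrt(se_p(oth$sensitivity, oth$n_malignant)^2 +
                            se_p(ref$sensitivity, ref$n_malignant)^2),
    d_specificity = oth$specificity - ref$specificity,
    se_specificity = sqrt(se_p(oth$specificity, oth$n_benign)^2 +
                            se_p(ref$specificity, ref$n_benign)^2),
    d_mean_surveillance = oth$mean_surveillance - ref$mean_surveillance,
    se_mean_surveillance = sqrt(
      oth$sd_surveillance^2 / (oth$n_malignant + oth$n_benign) +
        ref$sd_surveillance^2 / (ref$n_malignant + ref$n_benign)),
    stringsAsFactors = FALSE)
}
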