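#' Constants of the simplified BTS management pathway
#'
#' Diameter-based triage and surveillance rules. At baseline, nodules
#' measured under 5 mm (or flagged as clearly benign) are discharged;
#' solid nodules measured in \[5,6) mm go to a 12-month CT, in \[6,8) mm to
#' a 3-month CT, and at >= 8 mm face a baseline referral draw for
#' definitive management (91.8% if malignant, 17.1% if benign, standing in
#' for a high malignancy risk score); non-referred >= 8 mm nodules default
#' to the 12-month scan. Sub-solid nodules measured >= 5 mm are scanned at
#' 3, 12, 24 and 48 months. At solid follow-up scans the volume doubling
#' time (VDT, spherical assumption) against the previous attended scan
#' drives the decision: VDT <= 400 days refers for definitive management;
#' VDT in (400, 600\] days at 1 year earns a 2-year scan; slower growth is
#' discharged (at 1 year if VDT > 600 days, at 2 years if VDT > 400 days);
#' a measured decrease discharges. Sub-solid nodules are referred when the
#' measured diameter increases by more than 2 mm since the previous
#' attended scan, otherwise discharged at 4 years.
#'
#' For rounding readers the integer measurements make the bands: 5 mm ->
#' 12-month, 6-7 mm -> 3-month, >= 8 mm -> referral draw; the continuous
#' half-open bands apply to the true-size reader.
#'
#' @param discharge_below_mm Baseline discharge threshold (mm).
#' @param twelve_month_band,three_month_band Solid baseline bands (mm).
#' @param referral_min_mm Baseline referral band lower bound (mm).
#' @param referral_prob_malignant,referral_prob_benign Referral
#'   probabilities for >= 8 mm solid nodules.
#' @param vdt_dm_days VDT at or below which a nodule is referred (days).
#' @param vdt_continue_days Upper VDT bound (days) for continued
#'   surveillance at the 1-year scan.
#' @param solid_schedule,subsolid_schedule Scan times in months.
#' @param subsolid_growth_mm Sub-solid growth trigger (mm, strict).
#' @param days_per_month Calendar conversion (365.25 / 12).
#' @param unreferred_routing Where non-referred >= 8 mm solid nodules go:
#'   `"twelve_month"` (default) or `"three_month"`.
#' @param solid_shrink `"any_decrease"` (default) discharges a solid nodule
#'   whose measurement decreased; `"off"` disables early shrink discharge.
#' @param subsolid_shrink `"off"` (default), `"any_decrease"` or
#'   `"decrease_gt_2mm"`: early-discharge rule for sub-solid shrinkage.
#' @return A list of class `"pathway_constants"`.
#' @export
pathway_constants <- function(discharge_below_mm = 5,
                              twelve_month_band = c(5, 6),
                              three_month_band = c(6, 8),
                              referral_min_mm = 8,
                              referral_prob_malignant = 0.918,
                              referral_prob_benign = 0.171,
                              vdt_dm_days = 400,
                              vdt_continue_days = 600,
                              solid_schedule = c(0, 3, 12, 24),
                              subsolid_schedule = c(0, 3, 12, 24, 48),
                              subsolid_growth_mm = 2,
                              days_per_month = 30.4375,
                              unreferred_routing = c("twelve_month",
                                                     "three_month"),
                              solid_shrink = c("any_decrease", "off"),
                              subsolid_shrink = c("off", "any_decrease",
                                                  "decrease_gt_2mm")) {
  stopifnot(all(diff(solid_schedule) > 0), solid_schedule[1] == 0,
            all(diff(subsolid_schedule) > 0), subsolid_schedule[1] == 0,
            vdt_dm_days > 0, vdt_continue_days > vdt_dm_days)
  structure(list(
    discharge_below_mm = discharge_below_mm,
    twelve_month_band = twelve_month_band,
    three_month_band = three_month_band,
    referral_min_mm = referral_min_mm,
    referral_prob_malignant = referral_prob_malignant,
    referral_prob_benign = referral_prob_benign,
    vdt_dm_days = vdt_dm_days,
    vdt_continue_days = vdt_continue_days,
    solid_schedule = solid_schedule,
    subsolid_schedule = subsolid_schedule,
    subsolid_growth_mm = subsolid_growth_mm,
    days_per_month = days_per_month,
    unreferred_routing = match.arg(unreferred_routing),
    solid_shrink = match.arg(solid_shrink),
    subsolid_shrink = match.arg(subsolid_shrink)
  ), class = "pathway_constants")
}

#' Volume doubling time from two diameter measurements
#'
#' Assuming spherical form, `VDT = delta_days * log(2) / (3 * log(d2/d1))`
#' days. Equal diameters give `Inf` (no growth); a decrease gives a
#' negative value, interpreted by the pathway as shrinkage.
#'
#' @param d1,d2 Diameters (mm) at the earlier and later scan.
#' @param delta_days Days elapsed between the scans.
#' @return VDT in days (vectorized).
#' @export
#' @examples
#' vdt_days(6, 7, 91.3125)  # about 137 days
vdt_days <- function(d1, d2, delta_days) {
  if (any(d1 <= 0) || any(d2 <= 0) || any(delta_days <= 0))
    stop("diameters and delta_days must be > 0")
  out <- delta_days * log(2) / (3 * log(d2 / d1))
  out[d2 == d1] <- Inf
  out
}

# --- vectorized engine ------------------------------------------------------

# Simulate the whole pathway for one reader over a cohort, consuming the
# pre-generated draws. Returns one row per nodule.
simulate_reader <- function(cohort, reader, constants, draws) {
  cons <- constants
  n <- nrow(cohort)
  times <- draws$times
  tcol <- function(t) match(t, times)
  dpm <- cons$days_per_month

  d0 <- cohort$true_d0
  sub <- is_subsolid(cohort$subtype)
  mal <- cohort$malignant
  benf <- cohort$benign_features
  cap <- attr(cohort, "growth_cap")
  if (is.null(cap)) cap <- 30

  true_at <- function(idx, t) {
    d <- d0[idx]
    g1 <- mal[idx] & !sub[idx]
    if (any(g1)) d[g1] <- gompertz_diameter(d0[idx][g1], t,
                                            cohort$g_dinf[idx][g1],
                                            cohort$g_alpha[idx][g1])
    g2 <- mal[idx] & sub[idx]
    if (any(g2)) d[g2] <- linear_diameter(d0[idx][g2], t,
                                          cohort$g_rate[idx][g2], cap)
    d
  }

  disp <- character(n)
  dtime <- rep(NA_real_, n)
  nsc <- rep(1L, n)

  # baseline triage
  m0 <- measure(d0, reader, draws$noise[, tcol(0)])
  dc0 <- m0 < cons$discharge_below_mm | benf
  p_ref <- ifelse(mal, cons$referral_prob_malignant, cons$referral_prob_benign)
  refer <- !sub & !dc0 & m0 >= cons$referral_min_mm & draws$referral < p_ref
  disp[dc0] <- "DC"; dtime[dc0] <- 0
  disp[refer] <- "DM"; dtime[refer] <- 0

  route12 <- cons$unreferred_routing == "twelve_month"
  unref <- !sub & !dc0 & !refer & m0 >= cons$referral_min_mm
  to12 <- !sub & !dc0 & !refer &
    (m0 >= cons$twelve_month_band[1] & m0 < cons$twelve_month_band[2])
  to3s <- !sub & !dc0 & !refer &
    (m0 >= cons$three_month_band[1] & m0 < cons$three_month_band[2])
  if (route12) to12 <- to12 | unref else to3s <- to3s | unref
  to3ss <- sub & !dc0  # all retained sub-solid (measured >= 5)

  scan <- function(idx, prev_m, t) {
    m <- measure(true_at(idx, t), reader, draws$noise[idx, tcol(t)])
    nsc[idx] <<- nsc[idx] + 1L
    m
  }
  finish <- function(idx, what, t) {
    disp[idx] <<- what
    dtime[idx] <<- t
  }

  # solid surveillance ------------------------------------------------------
  sched <- cons$solid_schedule
  idx3 <- which(to3s)
  p12_idx <- which(to12)
  p12_prev <- m0[p12_idx]
  p12_pt <- rep(0, length(p12_idx))

  if (length(idx3)) {
    t <- sched[2]                         # 3-month scan
    m <- scan(idx3, m0[idx3], t)
    prev <- m0[idx3]
    shr <- cons$solid_shrink == "any_decrease" & m < prev
    v <- vdt_days(prev, pmax(m, 1e-9), t * dpm)
    dm <- !shr & m > prev & v <= cons$vdt_dm_days
    cont <- !shr & !dm
    finish(idx3[shr], "DC", t)
    finish(idx3[dm], "DM", t)
    p12_idx <- c(p12_idx, idx3[cont])
    p12_prev <- c(p12_prev, m[cont])
    p12_pt <- c(p12_pt, rep(t, sum(cont)))
  }

  if (length(p12_idx)) {
    t <- sched[3]                         # 12-month scan
    m <- scan(p12_idx, p12_prev, t)
    shr <- cons$solid_shrink == "any_decrease" & m < p12_prev
    v <- vdt_days(p12_prev, pmax(m, 1e-9), (t - p12_pt) * dpm)
    dm <- !shr & m > p12_prev & v <= cons$vdt_dm_days
    cont <- !shr & !dm & m > p12_prev & v <= cons$vdt_continue_days
    finish(p12_idx[dm], "DM", t)
    finish(p12_idx[!dm & !cont], "DC", t)
    p24_idx <- p12_idx[cont]
    p24_prev <- m[cont]
    p24_pt <- rep(t, sum(cont))
    if (length(p24_idx)) {
      t <- sched[4]                       # 24-month scan
      m <- scan(p24_idx, p24_prev, t)
      shr <- cons$solid_shrink == "any_decrease" & m < p24_prev
      v <- vdt_days(p24_prev, pmax(m, 1e-9), (t - p24_pt) * dpm)
      dm <- !shr & m > p24_prev & v <= cons$vdt_dm_days
      finish(p24_idx[dm], "DM", t)
      finish(p24_idx[!dm], "DC", t)
    }
  }

  # sub-solid surveillance --------------------------------------------------
  ss_idx <- which(to3ss)
  ss_prev <- m0[ss_idx]
  ss_sched <- cons$subsolid_schedule[-1]
  for (k in seq_along(ss_sched)) {
    if (!length(ss_idx)) break
    t <- ss_sched[k]
    m <- scan(ss_idx, ss_prev, t)
    delta <- m - ss_prev
    dm <- delta > cons$subsolid_growth_mm
    shr <- switch(cons$subsolid_shrink,
                  off = rep(FALSE, length(delta)),
                  any_decrease = !dm & delta < 0,
                  decrease_gt_2mm = !dm & delta < -cons$subsolid_growth_mm)
    finish(ss_idx[dm], "DM", t)
    finish(ss_idx[shr], "DC", t)
    cont <- !dm & !shr
    if (k == length(ss_sched)) {
      finish(ss_idx[cont], "DC", t)
    } else {
      ss_idx <- ss_idx[cont]
      ss_prev <- m[cont]
    }
  }

  stopifnot(!anyNA(dtime))
  data.frame(nodule_id = cohort$id,
             reader_id = reader$reader_id,
             disposition = disp,
             decision_time = dtime,
             n_scans = nsc,
             stringsAsFactors = FALSE)
}

# --- per-nodule reference engine -------------------------------------------

#' Run one nodule through the management pathway (reference engine)
#'
#' A readable per-nodule event loop used as the equivalence oracle for the
#' vectorized engine, and to obtain full scan histories. Consumes the same
#' pre-generated draws as the vectorized engine.
#'
#' @param nodule One-row cohort data frame (with growth columns for
#'   malignant nodules).
#' @param reader One row of [reader_defaults()].
#' @param constants A [pathway_constants()].
#' @param noise Named numeric vector of measurement noise, one entry per
#'   scheduled time (names `"0"`, `"3"`, ...).
#' @param referral_u Uniform draw in \[0,1) for the baseline referral.
#' @return A list with `disposition` (`"DM"` or `"DC"`), `decision_time`
#'   (months) and `scans` (data frame of attended `time`/`measured`).
#' @export
run_pathway <- function(nodule, reader, constants, noise, referral_u) {
  cons <- constants
  sub <- is_subsolid(nodule$subtype)
  cap <- attr(nodule, "growth_cap")
  if (is.null(cap)) cap <- 30
  truth <- function(t) {
    if (!isTRUE(nodule$malignant) || t == 0) return(nodule$true_d0)
    if (sub) linear_diameter(nodule$true_d0, t, nodule$g_rate, cap)
    else gompertz_diameter(nodule$true_d0, t, nodule$g_dinf, nodule$g_alpha)
  }
  mfun <- function(t) measure(truth(t), reader, noise[[as.character(t)]])
  scans <- data.frame(time = 0, measured = mfun(0))
  m0 <- scans$measured[1]
  done <- function(what, t) list(disposition = what, decision_time = t,
                                 scans = scans)

  # baseline triage
  if (m0 < cons$discharge_below_mm || isTRUE(nodule$benign_features))
    return(done("DC", 0))
  if (!sub && m0 >= cons$referral_min_mm) {
    p <- if (isTRUE(nodule$malignant)) cons$referral_prob_malignant
         else cons$referral_prob_benign
    if (referral_u < p) return(done("DM", 0))
    nxt <- if (cons$unreferred_routing == "twelve_month")
      cons$solid_schedule[3] else cons$solid_schedule[2]
  } else if (!sub) {
    nxt <- if (m0 >= cons$three_month_band[1]) cons$solid_schedule[2]
           else cons$solid_schedule[3]
  } else {
    nxt <- cons$subsolid_schedule[2]
  }

  prev_m <- m0; prev_t <- 0
  repeat {
    t <- nxt
    m <- mfun(t)
    scans <- rbind(scans, data.frame(time = t, measured = m))
    if (!sub) {
      if (cons$solid_shrink == "any_decrease" && m < prev_m)
        return(done("DC", t))
      v <- vdt_days(prev_m, max(m, 1e-9), (t - prev_t) * cons$days_per_month)
      if (m > prev_m && v <= cons$vdt_dm_days) return(done("DM", t))
      sched <- cons$solid_schedule
      if (t == sched[2]) {                       # 3-month scan
        nxt <- sched[3]
      } else if (t == sched[3]) {                # 12-month scan
        if (m > prev_m && v <= cons$vdt_continue_days) nxt <- sched[4]
        else return(done("DC", t))
      } else {                                   # 24-month scan
        return(done("DC", t))
      }
    } else {
      delta <- m - prev_m
      if (delta > cons$subsolid_growth_mm) return(done("DM", t))
      if ((cons$subsolid_shrink == "any_decrease" && delta < 0) ||
          (cons$subsolid_shrink == "decrease_gt_2mm" &&
           delta < -cons$subsolid_growth_mm))
        return(done("DC", t))
      sched <- cons$subsolid_schedule
      pos <- match(t, sched)
      if (pos == length(sched)) return(done("DC", t))
      nxt <- sched[pos + 1]
    }
    prev_m <- m; prev_t <- t
  }
}

#' Run the full pathway for a cohort under one or more readers
#'
#' For each reader, pre-generates that reader's measurement noise and
#' referral draws from its own substream, then simulates every nodule's
#' pathway to its final disposition. The default engine is vectorized; the
#' `"reference"` engine runs the per-nodule event loop on the same draws
#' and must agree field for field.
#'
#' @param cohort Cohort with malignancy, benign-feature flags and (for
#'   malignant nodules) growth parameters assigned.
#' @param readers Data frame of reader profiles ([reader_defaults()] or a
#'   subset of its rows).
#' @param constants A [pathway_constants()].
#' @param seed Master seed (per-reader substreams are derived from it).
#' @param engine `"vectorized"` (default) or `"reference"`.
#' @return A data frame with one row per nodule per reader: `nodule_id`,
#'   `reader_id`, `disposition` (`"DM"`/`"DC"`), `decision_time` (months)
#'   and `n_scans` (attended scans including baseline).
#' @export
run_population <- function(cohort, readers = reader_defaults(),
                           constants = pathway_constants(), seed = 1,
                           engine = c("vectorized", "reference")) {
  engine <- match.arg(engine)
  if (anyNA(cohort$malignant) || anyNA(cohort$benign_features))
    stop("cohort must have malignancy and benign-feature flags assigned")
  if (any(cohort$malignant) && is.null(cohort$g_alpha))
    stop("malignant nodules present but no growth parameters; run sample_growth()")
  times <- sort(unique(c(constants$solid_schedule, constants$subsolid_schedule)))
  out <- vector("list", nrow(readers))
  for (i in seq_len(nrow(readers))) {
    reader <- readers[i, , drop = FALSE]
    draws <- reader_draws(nrow(cohort), reader, seed, times)
    out[[i]] <- if (engine == "vectorized") {
      simulate_reader(cohort, reader, constants, draws)
    } else {
      rows <- lapply(seq_len(nrow(cohort)), function(j) {
        nd <- cohort[j, , drop = FALSE]
        attr(nd, "growth_cap") <- attr(cohort, "growth_cap")
        noise <- draws$noise[j, ]
        names(noise) <- as.character(times)
        res <- run_pathway(nd, reader, constants, noise, draws$referral[j])
        data.frame(nodule_id = nd$id, reader_id = reader$reader_id,
                   disposition = res$disposition,
                   decision_time = res$decision_time,
                   n_scans = nrow(res$scans),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
  }
  do.call(rbind, out)
}
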