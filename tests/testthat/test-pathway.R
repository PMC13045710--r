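r_true <- function() reader_defaults()[1, ]
r_round <- function() list(reader_id = "RR", bias_mm = 0, sd_mm = 0,
                           rounds_to_mm = TRUE)
no_noise <- c("0" = 0, "3" = 0, "12" = 0, "24" = 0, "48" = 0)

solid_nodule <- function(d0, malignant = FALSE, alpha = NA, dinf = NA,
                         features = FALSE) {
  data.frame(id = 1L,
             subtype = factor("solid", c("solid", "part_solid", "non_solid")),
             true_d0 = d0, malignant = malignant, benign_features = features,
             g_alpha = alpha, g_dinf = dinf, g_rate = NA_real_)
}
subsolid_nodule <- function(d0, malignant = FALSE, rate = NA) {
  data.frame(id = 1L,
             subtype = factor("part_solid", c("solid", "part_solid", "non_solid")),
             true_d0 = d0, malignant = malignant, benign_features = FALSE,
             g_alpha = NA_real_, g_dinf = NA_real_, g_rate = rate)
}

test_that("volume doubling time follows the spherical diameter formula", {
  expect_identical(vdt_days(6, 6, 100), Inf)
  expect_equal(vdt_days(6, 7, 91.3125), 136.864, tolerance = 1e-3)
  expect_equal(vdt_days(5, 6, 365.25), 462.867, tolerance = 1e-3)
  expect_lt(vdt_days(7, 6, 100), 0)   # shrinkage: negative, caller interprets
  expect_error(vdt_days(0, 6, 100), "must be > 0")
  expect_error(vdt_days(6, 7, 0), "must be > 0")
})

test_that("baseline triage routes boundary diameters per the band rules", {
  cons <- pathway_constants()
  go <- function(d0, u = 0.999, ...) {
    run_pathway(solid_nodule(d0, ...), r_true(), cons, no_noise, u)
  }
  # < 5 mm: discharged immediately
  expect_equal(go(4.99)[c("disposition", "decision_time")],
               list(disposition = "DC", decision_time = 0))
  # [5, 6): 12-month scan; benign and stable -> discharged there
  res5 <- go(5)
  expect_equal(res5$disposition, "DC")
  expect_equal(res5$decision_time, 12)
  expect_equal(res5$scans$time, c(0, 12))
  # [6, 8): 3-month scan first; stable benign continues to 12 then out
  for (d in c(6, 7.99)) {
    res <- go(d)
    expect_equal(res$scans$time, c(0, 3, 12))
    expect_equal(res$disposition, "DC")
    expect_equal(res$decision_time, 12)
  }
  # >= 8: referral draw at baseline; non-referred go to the 12-month scan
  expect_equal(go(8, u = 0)[c("disposition", "decision_time")],
               list(disposition = "DM", decision_time = 0))
  expect_equal(go(30, u = 0.999)$scans$time, c(0, 12))
  # clearly benign features discharge regardless of size
  expect_equal(go(12, u = 0, features = TRUE)$decision_time, 0)
  expect_equal(go(12, u = 0, features = TRUE)$disposition, "DC")
})

test_that("rounded readers see integer bands (5 -> 1 yr, 6-7 -> 3 mo, 8 -> referral)", {
  cons <- pathway_constants()
  first_follow <- function(d0, u = 0.999) {
    run_pathway(solid_nodule(d0), r_round(), cons, no_noise, u)$scans$time[2]
  }
  expect_equal(run_pathway(solid_nodule(4.49), r_round(), cons, no_noise,
                           0.999)$decision_time, 0)  # rounds to 4: discharged
  expect_equal(first_follow(5.4), 12)   # measures 5
  expect_equal(first_follow(5.5), 3)    # measures 6
  expect_equal(first_follow(7.4), 3)    # measures 7
  expect_equal(run_pathway(solid_nodule(7.5), r_round(), cons, no_noise,
                           0)$disposition, "DM")  # measures 8: referral draw
})

test_that("solid follow-up applies the VDT rules against the previous scan", {
  cons <- pathway_constants()
  # fast malignant growth: VDT well under 400 days at the 3-month scan
  fast <- run_pathway(solid_nodule(6, TRUE, alpha = 0.06, dinf = 100),
                      r_true(), cons, no_noise, 0.999)
  expect_equal(fast$disposition, "DM")
  expect_equal(fast$decision_time, 3)
  # slow growth: VDT in (400, 600] at 1 year earns the 2-year scan
  # alpha chosen so the 0->12-month VDT is ~500 days for d0 = 5.5
  a <- uniroot(function(a) {
    d12 <- gompertz_diameter(5.5, 12, 100, a)
    vdt_days(5.5, d12, 365.25) - 500
  }, c(1e-4, 0.1))$root
  slow <- run_pathway(solid_nodule(5.5, TRUE, alpha = a, dinf = 100),
                      r_true(), cons, no_noise, 0.999)
  expect_equal(slow$scans$time, c(0, 12, 24))
  # Gompertz deceleration: by 2 years VDT > 400, so discharged at 24 months
  expect_equal(slow$disposition, "DC")
  expect_equal(slow$decision_time, 24)
  # a measured decrease at a follow-up scan discharges
  shrunk <- run_pathway(solid_nodule(6.4), r_round(), cons,
                        c("0" = 0.2, "3" = -1.0, "12" = 0, "24" = 0, "48" = 0),
                        0.999)
  expect_equal(shrunk$disposition, "DC")
  expect_equal(shrunk$decision_time, 3)
  expect_equal(shrunk$scans$measured, c(7, 5))
})

test_that("sub-solid surveillance triggers only on > 2 mm growth", {
  cons <- pathway_constants()
  # +3 mm by the 3-month scan: definitive management there
  dm <- run_pathway(subsolid_nodule(10, TRUE, rate = 1.1), r_true(), cons,
                    no_noise, 0.999)
  expect_equal(dm$disposition, "DM")
  expect_equal(dm$decision_time, 3)
  # an increase of exactly 2 mm is not a trigger (strict inequality)
  ex2 <- run_pathway(subsolid_nodule(10),
                     list(reader_id = "RX", bias_mm = 0, sd_mm = 0,
                          rounds_to_mm = FALSE), cons,
                     c("0" = 0, "3" = 2, "12" = 2, "24" = 2, "48" = 2),
                     0.999)
  expect_equal(ex2$disposition, "DC")   # each step is exactly +2 vs previous? no:
  # measured 10, 12, 12, 12, 12 -> deltas 2, 0, 0, 0 -> monitored to 4 years
  expect_equal(ex2$decision_time, 48)
  expect_equal(ex2$scans$time, c(0, 3, 12, 24, 48))
  # stable benign sub-solid: discharged exactly at 48 months
  stable <- run_pathway(subsolid_nodule(10), r_true(), cons, no_noise, 0.999)
  expect_equal(stable$disposition, "DC")
  expect_equal(stable$decision_time, 48)
  # by default shrinkage does not discharge a sub-solid nodule early
  noisy <- run_pathway(subsolid_nodule(10),
                       list(reader_id = "RX", bias_mm = 0, sd_mm = 0,
                            rounds_to_mm = FALSE), cons,
                       c("0" = 0, "3" = -2, "12" = 0, "24" = 0, "48" = 0),
                       0.999)
  expect_equal(noisy$decision_time, 48)
  # but the any-decrease variant does
  cons2 <- pathway_constants(subsolid_shrink = "any_decrease")
  noisy2 <- run_pathway(subsolid_nodule(10),
                        list(reader_id = "RX", bias_mm = 0, sd_mm = 0,
                             rounds_to_mm = FALSE), cons2,
                        c("0" = 0, "3" = -2, "12" = 0, "24" = 0, "48" = 0),
                        0.999)
  expect_equal(noisy2$disposition, "DC")
  expect_equal(noisy2$decision_time, 3)
})

test_that("benign nodules under the true-size reader are never referred after baseline", {
  cohort <- make_test_cohort(20000, seed = 41)
  benign <- cohort[!cohort$malignant, ]
  out <- run_population(benign, reader_defaults()[1, ], seed = 41)
  late_dm <- out$disposition == "DM" & out$decision_time > 0
  expect_equal(sum(late_dm), 0)
  # solid benign under surveillance all leave at the 12-month scan,
  # sub-solid benign survivors exactly at 48 months
  sub <- benign$subtype %in% c("part_solid", "non_solid")
  surv <- out$decision_time > 0
  expect_true(all(out$decision_time[surv & !sub] == 12))
  expect_true(all(out$decision_time[surv & sub] == 48))
})

test_that("fast-growing cancers that survive baseline triage are always detected", {
  cohort <- make_fixtures("all_cancer_fast_growth", n = 1000, seed = 42)
  out <- run_population(cohort, reader_defaults()[1, ], seed = 42)
  baseline_dc <- out$disposition == "DC" & out$decision_time == 0
  expect_true(all(out$disposition[!baseline_dc] == "DM"))
  # everything routed to the 3-month scan is referred there
  three <- out$decision_time == 3
  expect_true(all(out$disposition[three] == "DM"))
})

test_that("vectorized engine agrees with the per-nodule reference engine", {
  cohort <- make_test_cohort(400, seed = 43)
  vec <- run_population(cohort, reader_defaults(), seed = 43,
                        engine = "vectorized")
  ref <- run_population(cohort, reader_defaults(), seed = 43,
                        engine = "reference")
  expect_equal(vec, ref, ignore_attr = TRUE)
})

test_that("population runs are reproducible and substream-isolated", {
  cohort <- make_test_cohort(2000, seed = 44)
  a <- run_population(cohort, reader_defaults(), seed = 44)
  b <- run_population(cohort, reader_defaults(), seed = 44)
  expect_identical(a, b)
  # R4 outcomes are identical whether run alone or with all readers
  solo <- run_population(cohort, reader_defaults()[5, ], seed = 44)
  expect_equal(a[a$reader_id == "R4", ], solo, ignore_attr = TRUE)
})

test_that("cohorts without assigned flags or growth are rejected", {
  cohort <- sample_cohort(100, seed = 45)
  expect_error(run_population(cohort), "assigned")
  cohort <- assign_malignancy(cohort, seed = 45)
  cohort <- assign_benign_features(cohort, seed = 45)
  if (any(cohort$malignant))
    expect_error(run_population(cohort), "growth")
})
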