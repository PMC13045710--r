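test_that("sampled cohorts respect the diameter bounds and subtype weights", {
  n <- 50000
  cohort <- sample_cohort(n, seed = 11)
  expect_equal(nrow(cohort), n)
  expect_true(all(cohort$true_d0 > 3 & cohort$true_d0 <= 30))
  # subtype fractions within 4 binomial SEs of the configured weights
  w <- default_subtype_mixture()$weights
  for (st in names(w)) {
    obs <- mean(cohort$subtype == st)
    se <- sqrt(w[[st]] * (1 - w[[st]]) / n)
    expect_lt(abs(obs - w[[st]]), 4 * se + 1e-12)
  }
})

test_that("per-subtype empirical CDFs match the analytic truncated law", {
  n <- 100000
  m <- default_subtype_mixture()
  for (st in c("solid", "part_solid", "non_solid")) {
    cohort <- sample_cohort(n, single_subtype_mixture(st), seed = 12)
    ks <- suppressWarnings(
      ks.test(cohort$true_d0, function(q)
        ptrunc_shifted_lognormal(q, m$specs[[st]]))
    )
    expect_lt(unname(ks$statistic), 0.005)
  }
})

test_that("degenerate mixtures collapse to a point mass at shift + exp(meanlog)", {
  mix <- subtype_mixture(
    c(solid = 1, part_solid = 0, non_solid = 0),
    list(solid = lognormal_spec(1.5, 1e-6, shift = 3, max_diameter = 30),
         part_solid = lognormal_spec(1, 1, 3, 30),
         non_solid = lognormal_spec(1, 1, 3, 30)))
  cohort <- sample_cohort(500, mix, seed = 3)
  expect_true(all(abs(cohort$true_d0 - (3 + exp(1.5))) < 1e-4))
})

test_that("sampled truncated mean matches the closed-form oracle", {
  cohort <- sample_cohort(200000, single_subtype_mixture("solid"), seed = 13)
  mu <- mean_trunc_shifted_lognormal(
    lognormal_spec(-0.51, 3.8809, shift = 3, max_diameter = 30))
  se <- sd(cohort$true_d0) / sqrt(nrow(cohort))
  expect_lt(abs(mean(cohort$true_d0) - mu), 4 * se)
})

test_that("malignancy assignment follows the size-band prevalences", {
  n <- 200000
  cohort <- sample_cohort(n, seed = 14)
  cohort <- assign_malignancy(cohort, seed = 14)
  bands <- default_prevalence_bands()
  sub <- cohort$subtype %in% c("part_solid", "non_solid")
  for (cls in c("solid", "sub_solid")) {
    b <- bands[[cls]]
    in_cls <- if (cls == "solid") !sub else sub
    for (i in seq_len(nrow(b))) {
      sel <- in_cls & cohort$true_d0 >= b$lower[i] &
        (cohort$true_d0 < b$upper[i] | (i == nrow(b) & cohort$true_d0 <= b$upper[i]))
      if (sum(sel) < 50) next
      se <- sqrt(b$prob[i] * (1 - b$prob[i]) / sum(sel))
      expect_lt(abs(mean(cohort$malignant[sel]) - b$prob[i]), 4 * se)
    }
  }
})

test_that("deterministic prevalence bands give exact counts", {
  cohort <- sample_cohort(20000, seed = 15)
  zero <- list(solid = data.frame(lower = 3, upper = 30, prob = 0),
               sub_solid = data.frame(lower = 3, upper = 30, prob = 0))
  expect_equal(sum(assign_malignancy(cohort, zero, seed = 1)$malignant), 0)
  # probability-1 band over [8, 30] for solid; sub-solid all zero
  certain <- list(solid = data.frame(lower = c(3, 8), upper = c(8, 30),
                                     prob = c(0, 1)),
                  sub_solid = data.frame(lower = 3, upper = 30, prob = 0))
  got <- assign_malignancy(cohort, certain, seed = 1)
  solid8 <- cohort$subtype == "solid" & cohort$true_d0 >= 8
  expect_equal(sum(got$malignant), sum(solid8))
  expect_true(all(got$malignant == solid8))
})

test_that("diameters outside the configured bands are a configuration error", {
  cohort <- sample_cohort(1000, seed = 16)
  narrow <- list(solid = data.frame(lower = 3, upper = 10, prob = 0.01),
                 sub_solid = data.frame(lower = 3, upper = 30, prob = 0.01))
  expect_error(assign_malignancy(cohort, narrow, seed = 1), "outside")
})

test_that("benign-feature flags only mark large benign nodules", {
  cohort <- assign_malignancy(sample_cohort(100000, seed = 17), seed = 17)
  flagged <- assign_benign_features(cohort, rate = 0.10, seed = 17)
  bad <- flagged$benign_features & (flagged$malignant | flagged$true_d0 < 5)
  expect_equal(sum(bad), 0)
  eligible <- !flagged$malignant & flagged$true_d0 >= 5
  rate <- mean(flagged$benign_features[eligible])
  se <- sqrt(0.1 * 0.9 / sum(eligible))
  expect_lt(abs(rate - 0.10), 4 * se)
  # deterministic extremes
  expect_equal(sum(assign_benign_features(cohort, 0, seed = 1)$benign_features), 0)
  expect_equal(sum(assign_benign_features(cohort, 1, seed = 1)$benign_features),
               sum(eligible))
})

test_that("identical seeds reproduce the cohort bit for bit", {
  a <- make_test_cohort(5000, seed = 99)
  b <- make_test_cohort(5000, seed = 99)
  expect_identical(a, b)
  c <- make_test_cohort(5000, seed = 100)
  expect_false(identical(a$true_d0, c$true_d0))
})
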