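# Fully assigned cohort at the default (published) parameters.
make_test_cohort <- function(n, seed = 1) {
  build_cohort(default_config(n_nodules = n, seed = seed))
}

# A single-subtype mixture, for per-subtype distribution checks.
single_subtype_mixture <- function(which) {
  w <- c(solid = 0, part_solid = 0, non_solid = 0)
  w[which] <- 1
  m <- default_subtype_mixture()
  subtype_mixture(w, m$specs)
}

truth_of <- function(outcomes, cohort) {
  cohort$malignant[match(outcomes$nodule_id, cohort$id)]
}
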