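#' Build a fully assigned cohort from a configuration
#'
#' Samples subtypes and diameters, assigns malignancy and benign-feature
#' flags, and attaches growth parameters to malignant nodules, all from
#' the configuration's named substreams of the master seed.
#'
#' @param config A `"simulation_config"` (see [default_config()]).
#' @param n Optional override of `config$n_nodules`.
#' @return A cohort data frame ready for [run_population()].
#' @export
build_cohort <- function(config = default_config(), n = NULL) {
  if (is.null(n)) n <- config$n_nodules
  seed <- config$seed
  cohort <- sample_cohort(n, mixture_from_config(config), seed)
  cohort <- assign_malignancy(cohort, bands_from_config(config), seed)
  cohort <- assign_benign_features(cohort, config$cohort$benign_feature_rate,
                                   config$cohort$benign_feature_min_mm, seed)
  sample_growth(cohort, growth_from_config(config), seed)
}

#' Run a full simulation and write its artifacts
#'
#' Builds the cohort, runs every configured reader through the management
#' pathway, and writes `cohort.tsv`, `outcomes.tsv`, `table2.tsv`
#' (dispositions by timepoint), `table3.tsv` (accuracy summary) and
#' `manifest.json` to `out_dir`. Reruns with the same configuration and
#' seed produce byte-identical tables.
#'
#' @param config A `"simulation_config"`.
#' @param out_dir Output directory (created if needed).
#' @param readers Optional character vector of reader ids to run
#'   (default: all configured readers).
#' @return Invisibly, a list with the cohort, outcomes, both summary
#'   tables and the manifest.
#' @export
simulate_run <- function(config = default_config(), out_dir, readers = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- build_cohort(config)
  profiles <- readers_from_config(config)
  if (!is.null(readers)) {
    if (!all(readers %in% profiles$reader_id))
      stop("unknown reader id(s): ",
           paste(setdiff(readers, profiles$reader_id), collapse = ", "))
    profiles <- profiles[profiles$reader_id %in% readers, , drop = FALSE]
  }
  constants <- constants_from_config(config)
  outcomes <- run_population(cohort, profiles, constants, config$seed)
  t2 <- timepoint_table(outcomes, cohort)
  t3 <- accuracy_summary(outcomes, cohort)

  wtsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wtsv(data.frame(id = cohort$id, subtype = cohort$subtype,
                    true_d0_mm = cohort$true_d0,
                    malignant = cohort$malignant,
                    benign_features = cohort$benign_features), "cohort.tsv"),
    wtsv(outcomes, "outcomes.tsv"),
    wtsv(t2, "table2.tsv"),
    wtsv(t3, "table3.tsv")
  )

  cfg_file <- tempfile(fileext = ".yaml")
  save_config(config, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("lungnodesim")),
    seed = config$seed,
    n_nodules = config$n_nodules,
    config_hash = unname(tools::md5sum(cfg_file)),
    substream_seeds = stats::setNames(
      lapply(c("cohort", "malignancy", "features", "growth",
               paste0("reader/", profiles$reader_id)),
             function(s) substream_seed(config$seed, s)),
      c("cohort", "malignancy", "features", "growth",
        paste0("reader/", profiles$reader_id))),
    timestamp = format(Sys.time(), tz = "UTC"),
    output_checksums = as.list(tools::md5sum(paths))
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, outcomes = outcomes,
                 timepoints = t2, accuracy = t3, manifest = manifest))
}

#' Canned fixtures for tests and examples
#'
#' * `"boundary_sizes"`: a benign solid cohort with true diameters at the
#'   triage band edges (4.99, 5, 6, 7.99, 8, 30 mm).
#' * `"all_benign_stable"`: a mixed-subtype cohort of benign nodules.
#' * `"all_cancer_fast_growth"`: malignant nodules with growth fast enough
#'   that every survivor of baseline triage is referred at the first
#'   follow-up scan.
#' * `"paper_defaults_small"`: the default configuration scaled to 1000
#'   nodules.
#'
#' @param kind Fixture name.
#' @param n Cohort size for the cohort-valued fixtures.
#' @param seed Seed used by the cohort-valued fixtures.
#' @return A cohort data frame, or a `"simulation_config"` for
#'   `"paper_defaults_small"`.
#' @export
make_fixtures <- function(kind = c("boundary_sizes", "all_benign_stable",
                                   "all_cancer_fast_growth",
                                   "paper_defaults_small"),
                          n = 200, seed = 1) {
  kind <- match.arg(kind)
  finish <- function(cohort) {
    if (is.null(cohort$g_alpha)) {
      cohort$g_alpha <- NA_real_
      cohort$g_dinf <- NA_real_
      cohort$g_rate <- NA_real_
    }
    attr(cohort, "growth_cap") <- 30
    cohort
  }
  switch(kind,
    boundary_sizes = finish(data.frame(
      id = 1:6,
      subtype = factor(rep("solid", 6),
                       levels = c("solid", "part_solid", "non_solid")),
      true_d0 = c(4.99, 5, 6, 7.99, 8, 30),
      malignant = FALSE, benign_features = FALSE)),
    all_benign_stable = {
      cohort <- sample_cohort(n, seed = seed)
      cohort$malignant <- FALSE
      cohort$benign_features <- FALSE
      finish(cohort)
    },
    all_cancer_fast_growth = {
      cohort <- sample_cohort(n, seed = seed)
      cohort$malignant <- TRUE
      cohort$benign_features <- FALSE
      sub <- is_subsolid(cohort$subtype)
      cohort$g_alpha <- ifelse(sub, NA_real_, 1.0)   # near-doubling by 3 months
      cohort$g_dinf <- ifelse(sub, NA_real_, 100)
      cohort$g_rate <- ifelse(sub, 3.0, NA_real_)    # +9 mm by 3 months
      attr(cohort, "growth_cap") <- 30
      cohort
    },
    paper_defaults_small = default_config(n_nodules = 1000, seed = seed)
  )
}
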