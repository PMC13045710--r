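#' Default simulation configuration
#'
#' Every model input in one serializable structure: cohort mixture and
#' diameter models, size-band malignancy prevalence, benign-feature flag
#' rate, reader profiles, growth hyperparameters and pathway constants.
#' `sdlog_base` is the printed base value of each log-scale SD; with
#' `square_sdlog = TRUE` (default) the sampling SD is its square.
#'
#' @param n_nodules Cohort size.
#' @param seed Master seed.
#' @return A nested list of class `"simulation_config"`.
#' @export
default_config <- function(n_nodules = 1000000, seed = 1) {
  subtype_entry <- function(meanlog, base) {
    list(meanlog = meanlog, sdlog_base = base, square_sdlog = TRUE,
         shift_mm = 3, max_mm = 30)
  }
  gc <- growth_config()
  pc <- pathway_constants()
  cfg <- list(
    n_nodules = n_nodules,
    seed = seed,
    cohort = list(
      solid_fraction = 0.939,
      part_non_ratio = c(4, 5),
      subtypes = list(
        solid = subtype_entry(-0.51, 1.97),
        part_solid = subtype_entry(2.19, 0.87),
        non_solid = subtype_entry(1.03, 1.13)
      ),
      benign_feature_rate = 0.10,
      benign_feature_min_mm = 5,
      prevalence = list(
        solid = list(lower = c(3, 6, 8), upper = c(6, 8, 30),
                     prob = c(0.009, 0.011, 0.094)),
        sub_solid = list(lower = c(3, 5), upper = c(5, 30),
                         prob = c(0.004, 0.036))
      )
    ),
    readers = unname(split(reader_defaults(), seq_len(5))),
    growth = unclass(gc),
    pathway = unclass(pc)
  )
  cfg$readers <- lapply(cfg$readers, as.list)
  structure(cfg, class = "simulation_config")
}

check_scalar_type <- function(default, value, key) {
  ok <- if (is.numeric(default)) is.numeric(value)
        else if (is.logical(default)) is.logical(value)
        else if (is.character(default)) is.character(value)
        else TRUE
  if (!ok || anyNA(value))
    stop(sprintf("configuration key '%s' has invalid value (expected %s)",
                 key, class(default)[1]), call. = FALSE)
  value
}

merge_config <- function(default, user, path = "") {
  if (is.null(user)) return(default)
  if (!is.list(default)) {
    return(check_scalar_type(default, user, path))
  }
  if (is.null(names(default))) {
    # unnamed list (e.g. readers): replace wholesale, validating elements
    # against the structure of the first default element
    return(lapply(user, function(el)
      merge_config(default[[1]], el, paste0(path, "[]"))))
  }
  if (!is.list(user))
    stop(sprintf("configuration key '%s' must be a mapping",
                 sub("^\\.", "", path)), call. = FALSE)
  unknown <- setdiff(names(user), names(default))
  if (length(unknown))
    stop("unknown configuration key: ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "),
         call. = FALSE)
  for (nm in names(user)) {
    default[[nm]] <- merge_config(default[[nm]], user[[nm]],
                                  paste0(sub("^\\.", "", path), ".", nm))
  }
  default
}

#' Load a simulation configuration from a YAML file
#'
#' Missing keys are filled with the defaults of [default_config()]
#' (an empty file yields the full defaults); unknown keys and wrongly
#' typed values are rejected with the offending key named.
#'
#' @param path Path to a YAML file.
#' @return A validated `"simulation_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(unclass(default_config()), user)
  structure(cfg, class = "simulation_config")
}

#' Write a simulation configuration to a YAML file
#'
#' @param config A `"simulation_config"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path,
                   handlers = list(logical = yaml::verbatim_logical))
  invisible(path)
}

# --- builders from config ---------------------------------------------------

mixture_from_config <- function(config) {
  co <- config$cohort
  spec_of <- function(e) {
    sdlog <- if (isTRUE(e$square_sdlog)) e$sdlog_base^2 else e$sdlog_base
    lognormal_spec(e$meanlog, sdlog, e$shift_mm, e$max_mm)
  }
  sub <- 1 - co$solid_fraction
  r <- co$part_non_ratio / sum(co$part_non_ratio)
  subtype_mixture(
    weights = c(solid = co$solid_fraction, part_solid = sub * r[1],
                non_solid = sub * r[2]),
    specs = lapply(co$subtypes, spec_of)
  )
}

bands_from_config <- function(config) {
  lapply(config$cohort$prevalence, function(b)
    data.frame(lower = b$lower, upper = b$upper, prob = b$prob))
}

readers_from_config <- function(config) {
  do.call(rbind, lapply(config$readers, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
}

growth_from_config <- function(config) {
  do.call(growth_config, config$growth)
}

constants_from_config <- function(config) {
  do.call(pathway_constants, config$pathway)
}
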