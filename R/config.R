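#' Pipeline configuration
#'
#' Builds the full declarative configuration of the pipeline, with every
#' numeric parameter present at its default. Defaults mirror the study
#' protocol: 5-km thinning and a 5-record minimum, |r| <= 0.8 and VIF <= 5
#' collinearity screening, 10 replicates with a 75/25 split, 10,000
#' background points, 500 iterations, max-SSS binarization, the seven-threat
#' table, K initialized at 0.05 and calibrated by half-of-max, degradation
#' tiers (0.17, 0.31, 0.42, 0.55) with a 0.31 vulnerability cut, 50,000
#' detector points with 5 Jenks classes and manual pH breaks (5.5, 6.5,
#' 7.5), and 5 richness zones with the top three forming high suitability.
#' Unknown keys are rejected.
#'
#' @param ... overrides as `name = value` (nested lists merged shallowly by
#'   section).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 20100898,
    input_dir = NULL,          # NULL: generate the synthetic fixture
    outdir = NULL,             # NULL: tempdir-based artifact directory
    cell_area_km2 = 1,
    landscape = list(shape = c(200, 200), n_species = 12,
                     records_per_species = c(30, 300), bias_strength = 0,
                     spatial_range = 15),
    screen = list(thin_cell_km = 5, min_records = 5, bias_bandwidth = 5),
    collinearity = list(r_max = 0.8, vif_max = 5),
    sdm = list(n_replicates = 10, train_frac = 0.75, background_n = 10000,
               max_iter = 500, tol = 1e-5, reg_multiplier = 1.0, tau = 0.5,
               classes = c("linear", "quadratic"), resample = "subsample"),
    richness = list(k_zones = 5, high_zones = 3:5, jenks_sample_max = 10000),
    hq = list(threats = threat_table(), sensitivity = default_sensitivity(),
              habitat_scores = default_habitat_scores(), k_init = 0.05,
              z = 2.5, tier_thresholds = c(0.17, 0.31, 0.42, 0.55),
              vuln_threshold = 0.31, recompute_tiers_jenks = FALSE),
    geodetector = list(n_points = 50000, k = 5, alpha = 0.05,
                       ph_breaks = c(5.5, 6.5, 7.5)),
    pathways = list(names = c("highway", "railway", "river"), k_hotspot = 5)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- defaults
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && !is.data.frame(defaults[[nm]]) &&
        is.list(over[[nm]]) && !is.data.frame(over[[nm]])) {
      sub_bad <- setdiff(names(over[[nm]]), names(defaults[[nm]]))
      if (length(sub_bad)) {
        stop("unknown configuration key(s) in `", nm, "`: ",
             paste(sub_bad, collapse = ", "), call. = FALSE)
      }
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config must carry a seed", call. = FALSE)
  for (key in c("threats", "sensitivity", "habitat_scores")) {
    if (is.null(cfg$hq[[key]])) {
      stop("config is missing hq$", key, "; refusing to run", call. = FALSE)
    }
  }
  thr <- cfg$hq$threats
  stopifnot(all(c("threat", "d_max_km", "weight", "decay") %in% names(thr)))
  if (any(thr$d_max_km <= 0) || any(thr$weight <= 0) || any(thr$weight > 1)) {
    stop("threat table: d_max must be > 0 and weights in (0, 1]",
         call. = FALSE)
  }
  sens <- cfg$hq$sensitivity
  missing_threats <- setdiff(thr$threat, names(sens))
  if (length(missing_threats)) {
    stop("sensitivity matrix lacks threat column(s): ",
         paste(missing_threats, collapse = ", "), call. = FALSE)
  }
  svals <- as.matrix(sens[setdiff(names(sens), "lulc")])
  if (any(svals < 0 | svals > 1)) {
    stop("sensitivities must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a configuration from JSON
#'
#' @param path JSON file of overrides (same structure as
#'   [pipeline_config()] arguments).
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  over <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("threats", "sensitivity", "habitat_scores")) {
    if (!is.null(over$hq[[key]])) {
      over$hq[[key]] <- tibble::as_tibble(over$hq[[key]])
    }
  }
  do.call(pipeline_config, over)
}
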