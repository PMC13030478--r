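#' Run the integrated invasion-risk pipeline
#'
#' Executes the six analysis stages in order -- occurrence screening,
#' per-species suitability modelling, richness stacking and zoning, habitat
#' degradation and quality, geographical-detector attribution, and
#' core-habitat integration with protected-area gap analysis -- writing
#' each stage's rasters and tables plus a machine-readable run log (seed,
#' parameter hash, per-stage record counts and timings) to the artifact
#' directory. Outputs are a pure function of (inputs, config, seed); a
#' stage failure aborts with the stage named, retaining the artifacts
#' already written.
#'
#' @param config a `pipeline_config` (see [pipeline_config()]).
#' @param stages subset of
#'   `c("screen", "sdm", "richness", "hq", "geodetect", "integrate")`; later
#'   stages require earlier ones in the same call.
#' @param quiet suppress progress messages.
#' @return an object of class `pipeline_result`: list of stage outputs plus
#'   `outdir`, invisibly printable.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("screen", "sdm", "richness", "hq",
                                    "geodetect", "integrate"),
                         quiet = TRUE) {
  validate_config(config)
  op <- options(invrisk.quiet = quiet); on.exit(options(op))
  all_stages <- c("screen", "sdm", "richness", "hq", "geodetect", "integrate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  outdir <- config$outdir %||% file.path(tempdir(), "invrisk_run")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = config$seed,
              parameter_hash = rlang::hash(unclass(config)),
              stages = list())
  state <- list(config = config, outdir = outdir)

  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return(invisible())
    t0 <- proc.time()[["elapsed"]]
    state <<- tryCatch(fun(state), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log$stages[[name]] <<- c(state$stage_log %||% list(),
                             list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)))
    state$stage_log <<- NULL
    jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # inputs: bundled synthetic fixture or a directory written by write_landscape()
  state$bundle <- if (is.null(config$input_dir)) {
    do.call(synthetic_landscape, c(config$landscape, list(seed = config$seed)))
  } else {
    read_landscape(config$input_dir)
  }

  run_stage("screen", stage_screen)
  run_stage("sdm", stage_sdm)
  run_stage("richness", stage_richness)
  run_stage("hq", stage_hq)
  run_stage("geodetect", stage_geodetect)
  run_stage("integrate", stage_integrate)

  structure(state, class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a landscape bundle written by [write_landscape()]
#'
#' @param dir directory of ASCII grids, GeoJSON and CSV tables.
#' @return a `landscape_bundle`.
#' @export
read_landscape <- function(dir) {
  envs <- list.files(dir, pattern = "^env_.*\\.asc$", full.names = TRUE)
  env <- stats::setNames(lapply(envs, read_raster),
                         sub("^env_(.*)\\.asc$", "\\1", basename(envs)))
  lulc <- read_raster(file.path(dir, "lulc.asc"), kind = "categorical")
  thr_files <- list.files(dir, pattern = "^threat_.*\\.asc$", full.names = TRUE)
  threat_rasters <- stats::setNames(
    lapply(thr_files, read_raster),
    sub("^threat_(.*)\\.asc$", "\\1", basename(thr_files)))
  occ <- tibble::as_tibble(utils::read.csv(file.path(dir, "occurrences.csv")))
  pas <- read_geojson(file.path(dir, "protected_areas.geojson"))
  niche_path <- file.path(dir, "niche_truth.csv")
  niche <- if (file.exists(niche_path)) {
    tibble::as_tibble(utils::read.csv(niche_path))
  } else NULL
  structure(list(env = env, lulc = lulc, threat_rasters = threat_rasters,
                 threat_vectors = NULL, pas = pas, niche = niche,
                 occurrences = occ),
            class = "landscape_bundle")
}

stage_screen <- function(state) {
  cfg <- state$config; b <- state$bundle
  occ <- thin_and_filter(b$occurrences,
                         cell_km = cfg$screen$thin_cell_km,
                         min_records = cfg$screen$min_records)
  coll <- screen_collinearity(b$env, r_max = cfg$collinearity$r_max,
                              vif_max = cfg$collinearity$vif_max)
  bias <- build_bias_surface(occ, b$env[[1]],
                             bandwidth = cfg$screen$bias_bandwidth)
  background <- sample_background(bias, n = cfg$sdm$background_n,
                                  seed = cfg$seed + 10)
  dir.create(file.path(state$outdir, "screen"), showWarnings = FALSE)
  utils::write.csv(occ, file.path(state$outdir, "screen", "occ_retained.csv"),
                   row.names = FALSE)
  utils::write.csv(coll$report,
                   file.path(state$outdir, "screen", "collinearity.csv"),
                   row.names = FALSE)
  write_raster(bias, file.path(state$outdir, "screen", "bias.asc"))
  log <- attr(occ, "screen_log")
  state$occ <- occ
  state$env <- b$env[coll$retained]
  state$collinearity <- coll
  state$bias <- bias
  state$background <- background
  state$stage_log <- list(
    n_raw = log$n_records[1], n_retained = log$n_records[3],
    n_species = log$n_species[3], layers_retained = coll$retained,
    params = cfg$screen)
  state
}

stage_sdm <- function(state) {
  cfg <- state$config
  dir.create(file.path(state$outdir, "sdm"), showWarnings = FALSE)
  species <- sort(unique(state$occ$species))
  sdms <- list(); rows <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    rec <- state$occ[state$occ$species == sp, ]
    fit <- replicate_run(
      rec, state$env, state$background,
      n_replicates = cfg$sdm$n_replicates, train_frac = cfg$sdm$train_frac,
      resample = cfg$sdm$resample, seed = cfg$seed + 100 + i, species = sp,
      classes = cfg$sdm$classes, reg_multiplier = cfg$sdm$reg_multiplier,
      max_iter = cfg$sdm$max_iter, tol = cfg$sdm$tol, tau = cfg$sdm$tau)
    write_raster(fit$hsi, file.path(state$outdir, "sdm",
                                    paste0("hsi_", sp, ".asc")))
    write_raster(fit$binary, file.path(state$outdir, "sdm",
                                       paste0("binary_", sp, ".asc")))
    sdms[[sp]] <- fit
    rows[[sp]] <- glance(fit)
  }
  metrics <- dplyr::bind_rows(rows)
  utils::write.csv(metrics, file.path(state$outdir, "sdm", "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(metrics, file.path(state$outdir, "sdm", "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  state$sdms <- sdms
  state$sdm_metrics <- metrics
  state$stage_log <- list(n_species = length(species),
                          mean_test_auc = mean(metrics$auc_test),
                          params = cfg$sdm)
  state
}

stage_richness <- function(state) {
  cfg <- state$config
  dir.create(file.path(state$outdir, "richness"), showWarnings = FALSE)
  richness <- stack_binary(lapply(state$sdms, `[[`, "binary"))
  br <- jenks_breaks(richness$values, k = cfg$richness$k_zones,
                     sample_max = cfg$richness$jenks_sample_max,
                     seed = state$config$seed + 20)
  zones <- classify_zones(richness, br)
  mask <- if (zones$k == 5) {
    high_suitability_mask(zones)
  } else {
    # degenerate small stacks: keep the top-3/5 share of the reduced zoning
    lo <- max(2, zones$k - 2)
    map_raster(zones$zones, function(v) {
      out <- (v >= lo) + 0
      out[!is.finite(v)] <- NA_real_
      out
    }, kind = "continuous", codes = NULL)
  }
  write_raster(richness, file.path(state$outdir, "richness", "richness.asc"))
  write_raster(zones$zones, file.path(state$outdir, "richness", "zones.asc"))
  write_raster(mask, file.path(state$outdir, "richness", "high_suitability.asc"))
  jsonlite::write_json(list(breaks = as.numeric(br),
                            zone_areas = zone_areas(zones, cfg$cell_area_km2)),
                       file.path(state$outdir, "richness", "breaks.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  state$richness <- richness
  state$zones <- zones
  state$high_suit <- mask
  state$stage_log <- list(breaks = as.numeric(br),
                          suitable_cells = area_of(mask))
  state
}

stage_hq <- function(state) {
  cfg <- state$config; b <- state$bundle
  dir.create(file.path(state$outdir, "hq"), showWarnings = FALSE)
  thr <- cfg$hq$threats
  fields <- stats::setNames(lapply(seq_len(nrow(thr)), function(i) {
    nm <- thr$threat[i]
    src <- b$threat_rasters[[nm]]
    if (is.null(src)) stop("threat source layer missing: ", nm)
    threat_field(src, d_max_km = thr$d_max_km[i], decay = thr$decay[i])
  }), thr$threat)
  D <- degradation(fields, thr, cfg$hq$sensitivity, b$lulc)
  K <- calibrate_k(D, k_init = cfg$hq$k_init)
  Q <- quality(D, cfg$hq$habitat_scores, b$lulc, K = as.numeric(K),
               z = cfg$hq$z)
  if (isTRUE(cfg$hq$recompute_tiers_jenks)) {
    # synthetic landscapes: re-derive the tier cuts from this D distribution
    # and take "medium and above" (>= lower edge of tier 3) as vulnerable
    tiers_thr <- as.numeric(jenks_breaks(D$values, k = 5,
                                         seed = cfg$seed + 30))
    vuln_thr <- tiers_thr[2]
  } else {
    tiers_thr <- cfg$hq$tier_thresholds
    vuln_thr <- cfg$hq$vuln_threshold
  }
  cls <- classify_degradation(D, thresholds = tiers_thr,
                              vuln_threshold = vuln_thr)
  corr <- threat_correlations(D, fields, seed = cfg$seed + 31)
  write_raster(D, file.path(state$outdir, "hq", "degradation.asc"))
  write_raster(Q, file.path(state$outdir, "hq", "quality.asc"))
  write_raster(cls$tiers$zones, file.path(state$outdir, "hq", "tiers.asc"))
  write_raster(cls$high_vulnerability,
               file.path(state$outdir, "hq", "high_vulnerability.asc"))
  utils::write.csv(corr, file.path(state$outdir, "hq", "threat_correlations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(K = as.numeric(K), K_trace = attr(K, "trace"),
                            z = cfg$hq$z, tier_thresholds = tiers_thr),
                       file.path(state$outdir, "hq", "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  state$threat_fields <- fields
  state$D <- D; state$Q <- Q; state$K <- as.numeric(K)
  state$deg_tiers <- cls$tiers
  state$high_vuln <- cls$high_vulnerability
  state$threat_corr <- corr
  state$stage_log <- list(K = as.numeric(K), max_D = max(D$values, na.rm = TRUE))
  state
}

stage_geodetect <- function(state) {
  cfg <- state$config
  dir.create(file.path(state$outdir, "geodetect"), showWarnings = FALSE)
  pts <- sample_points(state$richness, state$env,
                       n = cfg$geodetector$n_points, seed = cfg$seed + 40)
  manual <- list()
  if ("SoilPH" %in% names(state$env)) manual$SoilPH <- cfg$geodetector$ph_breaks
  rep <- geodetect(pts, k = cfg$geodetector$k, manual_breaks = manual,
                   alpha = cfg$geodetector$alpha, seed = cfg$seed + 41)
  utils::write.csv(rep$factor,
                   file.path(state$outdir, "geodetect", "factor_q.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$interaction,
                   file.path(state$outdir, "geodetect", "interaction_q.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$ecological,
                   file.path(state$outdir, "geodetect", "ecological.csv"),
                   row.names = FALSE)
  utils::write.csv(pts, file.path(state$outdir, "geodetect", "sample_points.csv"),
                   row.names = FALSE)
  state$detector <- rep
  state$detector_sample <- pts
  state$stage_log <- list(n_points = nrow(pts),
                          top_q = max(rep$factor$q, na.rm = TRUE))
  state
}

stage_integrate <- function(state) {
  cfg <- state$config; b <- state$bundle
  dir.create(file.path(state$outdir, "integrate"), showWarnings = FALSE)
  priority <- core_habitat(state$high_suit, state$high_vuln)
  gap <- gap_analysis(priority, b$pas, cell_area = cfg$cell_area_km2,
                      lulc = b$lulc)
  path_names <- intersect(cfg$pathways$names, names(state$threat_fields))
  pr <- pathway_dominance(state$threat_fields[path_names], cfg$hq$threats,
                          cfg$hq$sensitivity, b$lulc,
                          k_hotspot = cfg$pathways$k_hotspot,
                          cell_area = cfg$cell_area_km2,
                          seed = cfg$seed + 50)
  write_raster(priority$map, file.path(state$outdir, "integrate", "priority.asc"))
  if (!is.null(pr$dominant)) {
    write_raster(pr$dominant,
                 file.path(state$outdir, "integrate", "dominant_pathway.asc"))
  }
  jsonlite::write_json(
    list(summary = gap$summary, composition = gap$composition,
         pathway = pr$summary),
    file.path(state$outdir, "integrate", "gap_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(gap$summary,
                   file.path(state$outdir, "integrate", "gap_report.csv"),
                   row.names = FALSE)
  state$priority <- priority
  state$gap <- gap
  state$pathways <- pr
  state$stage_log <- list(core_km2 = glance(gap)$core_km2,
                          gap_pct = glance(gap)$gap_pct)
  state
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> artifacts in ", x$outdir, "\n", sep = "")
  if (!is.null(x$sdm_metrics)) {
    cat(sprintf("  %d species, mean test AUC %.3f\n", nrow(x$sdm_metrics),
                mean(x$sdm_metrics$auc_test)))
  }
  if (!is.null(x$K)) cat(sprintf("  K = %.3f\n", x$K))
  if (!is.null(x$gap)) print(x$gap$summary)
  invisible(x)
}
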