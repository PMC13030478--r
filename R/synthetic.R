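#' Synthetic environmental layer stack
#'
#' Generates the ten continuous environmental layers the analysis expects
#' (Bio1, Bio2, Bio4, Bio12, Bio15, SoilPH, NDVI, CP, DMSP, RD), each the
#' sum of a large-scale directional gradient and Gaussian-smoothed noise
#' with correlation length `spatial_range` cells. DMSP and RD are passed
#' through an exponential transform so their marginals are right-skewed,
#' mimicking nighttime-light and road-density data. Layers are rescaled to
#' field-realistic units. Pairwise |r| < 0.8 is enforced by construction
#' check: an offending layer is regenerated with a fresh substream.
#'
#' With `spatial_range = 0` the layers are pure white noise (no gradient,
#' no smoothing), which is useful for autocorrelation null tests.
#'
#' @param shape `c(rows, cols)`, at least 50 x 50 unless `spatial_range` is
#'   0.
#' @param seed RNG seed (required; no hidden RNG state).
#' @param spatial_range smoothing length of the noise component, in cells.
#' @return named list of continuous `inv_raster`s.
#' @export
make_env_stack <- function(shape = c(200, 200), seed = NULL,
                           spatial_range = 15) {
  require_seed(seed)
  if (spatial_range > 0 && (shape[1] < 50 || shape[2] < 50)) {
    stop("shape must be at least 50 x 50 for autocorrelation to be expressible",
         call. = FALSE)
  }
  nr <- shape[1]; nc <- shape[2]
  specs <- list(
    Bio1  = list(lo = 2,   hi = 24,   skew = FALSE),  # deg C
    Bio2  = list(lo = 5,   hi = 15,   skew = FALSE),  # deg C
    Bio4  = list(lo = 300, hi = 1100, skew = FALSE),  # sd*100
    Bio12 = list(lo = 150, hi = 2400, skew = FALSE),  # mm
    Bio15 = list(lo = 20,  hi = 110,  skew = FALSE),  # CV
    SoilPH = list(lo = 4.6, hi = 8.6, skew = FALSE),
    NDVI  = list(lo = 0.02, hi = 0.95, skew = FALSE),
    CP    = list(lo = 0,   hi = 1,    skew = FALSE),  # cropland fraction
    DMSP  = list(lo = 0,   hi = 63,   skew = TRUE),   # nighttime light DN
    RD    = list(lo = 0,   hi = 6,    skew = TRUE)    # km per km^2
  )
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  gen_field <- function() {
    noise <- matrix(stats::rnorm(nr * nc), nr, nc)
    if (spatial_range == 0) return(noise)
    sm <- gauss_smooth(noise, spatial_range)
    sm <- (sm - mean(sm)) / stats::sd(sm)
    theta <- stats::runif(1, 0, 2 * pi)
    grad <- cos(theta) * (rows - nr / 2) / nr + sin(theta) * (cols - nc / 2) / nc
    amp <- stats::runif(1, 0.8, 2)
    g <- amp * grad / stats::sd(grad)
    g + sm
  }
  out <- with_seed(seed, {
    layers <- list()
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      best <- NULL; best_score <- Inf
      for (attempt in 1:12) {
        f <- gen_field()
        if (sp$skew) f <- exp(1.2 * scale01(f) * 3)  # right-skewed marginal
        v <- scale01(f) * (sp$hi - sp$lo) + sp$lo
        # construction check: the stack must clear the collinearity screen
        # (pairwise |r| < 0.8 and VIF < 5, with margin) with no removals
        cand <- c(lapply(layers, function(l) as.vector(l$values)),
                  list(as.vector(v)))
        cm <- abs(stats::cor(do.call(cbind, cand))); diag(cm) <- 0
        vif <- if (length(cand) >= 2) {
          tryCatch(diag(solve(stats::cor(do.call(cbind, cand)))),
                   error = function(e) Inf)
        } else 1
        score <- max(max(cm) / 0.7, max(vif) / 4)
        if (score < best_score) { best <- v; best_score <- score }
        if (max(cm) < 0.7 && max(vif) < 4) break
      }
      layers[[nm]] <- inv_raster(best, xmin = 0, ymax = nr, cellsize = 1)
    }
    layers
  })
  out
}

scale01 <- function(m) {
  r <- range(m)
  if (r[1] == r[2]) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

#' Synthetic 7-class land-use/land-cover map
#'
#' Derives the categorical landscape from the environmental stack: a
#' disturbance score (DMSP + RD + CP) drives the anthropogenic classes,
#' wetness (Bio12) and vegetation (NDVI) the natural ones. Codes:
#' 1 high-intensity disturbance, 2 degraded forestland, 3 shrubland,
#' 4 wetland, 5 degraded grassland, 6 transportation corridors,
#' 7 primary vegetation.
#'
#' @param env named list from [make_env_stack()].
#' @return categorical `inv_raster` with codes 1..7 (all present).
#' @export
make_lulc <- function(env) {
  dist_score <- scale01(env$DMSP$values) + scale01(env$RD$values) +
    scale01(env$CP$values)
  d <- scale01(dist_score)
  wet <- scale01(env$Bio12$values)
  veg <- scale01(env$NDVI$values)
  rd <- scale01(env$RD$values)
  lulc <- matrix(5L, nrow(d), ncol(d))            # degraded grassland default
  lulc[veg > 0.45] <- 2L                          # degraded forestland
  lulc[veg > 0.45 & veg <= 0.6 & wet < 0.4] <- 3L # shrubland
  lulc[veg > 0.75 & d < 0.5] <- 7L                # primary vegetation
  lulc[wet > 0.72 & d < 0.4] <- 4L  # wetland, kept away from disturbance
  lulc[rd > stats::quantile(rd, 0.92) & d <= stats::quantile(d, 0.9)] <- 6L
  lulc[d > stats::quantile(d, 0.9)] <- 1L         # high-intensity disturbance
  # guarantee every class is represented
  for (code in 1:7) {
    if (!any(lulc == code)) lulc[which.max(d == d)[1] + code - 1] <- code
  }
  inv_raster(lulc, xmin = env[[1]]$xmin, ymax = env[[1]]$ymax,
             cellsize = env[[1]]$cellsize, crs = env[[1]]$crs,
             kind = "categorical", codes = 1:7)
}

#' Synthetic niche parameters
#'
#' Gaussian (log-linear quadratic) niches: per species, 2-4 active
#' environmental variables with an optimum inside the observed range, a
#' breadth proportional to the layer's spread, and a weight. The
#' linear+quadratic maxent feature class can represent these truths
#' exactly, which makes parameter recovery a sharp test.
#'
#' @param env environmental stack.
#' @param n_species number of species.
#' @param seed RNG seed (required).
#' @param single_driver indices of species restricted to a single active
#'   variable (used for contribution-recovery tests); default: species 1.
#' @param breadth_range niche breadth range as a fraction of each layer's
#'   standard deviation.
#' @return tibble with `species`, `variable`, `optimum`, `breadth`, `weight`.
#' @export
make_niche_params <- function(env, n_species = 12, seed = NULL,
                              single_driver = 1L,
                              breadth_range = c(0.2, 0.45)) {
  require_seed(seed)
  vars <- names(env)
  probe_var <- if ("DMSP" %in% vars) "DMSP" else vars[1]
  with_seed(seed, dplyr::bind_rows(lapply(seq_len(n_species), function(s) {
    probe <- s %in% single_driver
    # the probe emulates a nightlight-driven invader (the dominant predictor
    # class in national invasion mapping); drawing it at random can land on
    # a variable spatially confounded with others on a given landscape
    k <- if (probe) 1L else sample(2:4, 1)
    active <- if (probe) probe_var else sample(vars, k)
    dplyr::bind_rows(lapply(active, function(v) {
      vals <- env[[v]]$values
      rng <- stats::quantile(vals, c(0.1, 0.9))
      tibble::tibble(
        species = sprintf("sp%02d", s),
        variable = v,
        optimum = stats::runif(1, rng[1], rng[2]),
        # the single-driver probe gets a narrow, heavy niche so that its
        # driving variable is unambiguously dominant
        breadth = stats::sd(vals) * if (probe) 0.12 else
          stats::runif(1, breadth_range[1], breadth_range[2]),
        weight = if (probe) 1.5 else stats::runif(1, 0.7, 1.3)
      )
    }))
  })))
}

#' True suitability field of a synthetic species
#'
#' exp of the Gaussian log-suitability. Because narrow niches underflow to
#' exactly zero far from the optimum, the log field is attached as
#' attribute `log_suitability`; rank-based comparisons (Spearman) should
#' use it, as ranks are invariant to the monotone exp transform.
#'
#' @param env environmental stack.
#' @param niche_sp niche rows of one species.
#' @return suitability `inv_raster` with attribute `log_suitability`.
#' @export
truth_suitability <- function(env, niche_sp) {
  ll <- 0
  for (i in seq_len(nrow(niche_sp))) {
    v <- env[[niche_sp$variable[i]]]$values
    ll <- ll - niche_sp$weight[i] *
      (v - niche_sp$optimum[i])^2 / (2 * niche_sp$breadth[i]^2)
  }
  out <- const_like(env[[1]], 0)
  out$values <- exp(ll)
  logr <- const_like(env[[1]], 0)
  logr$values <- matrix(ll, nrow(logr$values), ncol(logr$values))
  attr(out, "log_suitability") <- logr
  out
}

#' Synthetic observation-effort field
#'
#' A smoothed random field thresholded into "cities": effort is high inside
#' the top decile patches and low elsewhere, then re-smoothed, reproducing
#' the clustered sampling that target-group background correction addresses.
#'
#' @param grid template `inv_raster`.
#' @param seed RNG seed (required).
#' @param smooth smoothing length in cells.
#' @return `inv_raster` of positive effort weights (mean 1).
#' @export
make_effort_field <- function(grid, seed = NULL, smooth = 10) {
  require_seed(seed)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  with_seed(seed, {
    f <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc), smooth)
    cities <- f > stats::quantile(f, 0.9)
    eff <- gauss_smooth(ifelse(cities, 1, 0.03), smooth / 2)
    out <- const_like(grid, 0)
    out$values <- eff / mean(eff)
    out
  })
}

#' Synthetic occurrence records
#'
#' Draws presence records per species by weighted sampling of cells with
#' probability proportional to truth suitability times the observation
#' effort raised to `bias_strength`; coordinates are jittered uniformly
#' within the source cell. `bias_strength = 0` gives unbiased sampling.
#'
#' @param env environmental stack.
#' @param niche niche-parameter tibble from [make_niche_params()].
#' @param effort effort `inv_raster` (see [make_effort_field()]).
#' @param records_per_species integer range `c(lo, hi)` (lo >= 1) or a
#'   single count.
#' @param bias_strength exponent >= 0 on the effort field.
#' @param seed RNG seed (required).
#' @return tibble with `species`, `x`, `y`, `row`, `col`.
#' @export
make_occurrences <- function(env, niche, effort,
                             records_per_species = c(30, 300),
                             bias_strength = 1, seed = NULL) {
  require_seed(seed)
  if (records_per_species[1] < 1) {
    stop("lower bound of records_per_species must be >= 1", call. = FALSE)
  }
  if (length(records_per_species) == 1) {
    records_per_species <- rep(records_per_species, 2)
  }
  stopifnot(bias_strength >= 0)
  grid <- env[[1]]
  nr <- nrow(grid$values)
  eff_w <- as.vector(effort$values)^bias_strength
  with_seed(seed, dplyr::bind_rows(lapply(
    unique(niche$species), function(sp) {
      truth <- truth_suitability(env, niche[niche$species == sp, ])
      p <- as.vector(truth$values) * eff_w
      n <- if (records_per_species[1] == records_per_species[2]) {
        records_per_species[1]
      } else {
        sample(records_per_species[1]:records_per_species[2], 1)
      }
      idx <- sample(length(p), n, replace = TRUE, prob = p)
      row <- (idx - 1L) %% nr + 1L
      col <- (idx - 1L) %/% nr + 1L
      tibble::tibble(
        species = sp,
        x = grid$xmin + (col - 1) * grid$cellsize +
          stats::runif(n, 0, grid$cellsize),
        y = grid$ymax - (row - 1) * grid$cellsize -
          stats::runif(n, 0, grid$cellsize),
        row = row, col = col
      )
    })))
}

# random smooth polyline crossing the grid (for highways/railways/rivers)
random_polyline <- function(grid, n_knots = 8, wiggle = 0.15) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  W <- nc * grid$cellsize; H <- nr * grid$cellsize
  horizontal <- stats::runif(1) < 0.5
  ts <- seq(0, 1, length.out = n_knots)
  if (horizontal) {
    x <- grid$xmin + ts * W
    y0 <- grid$ymax - stats::runif(1, 0.2, 0.8) * H
    y <- y0 + cumsum(stats::rnorm(n_knots, 0, wiggle * H / n_knots)) * 3
    y <- pmin(pmax(y, grid$ymax - H), grid$ymax)
  } else {
    y <- grid$ymax - ts * H
    x0 <- grid$xmin + stats::runif(1, 0.2, 0.8) * W
    x <- x0 + cumsum(stats::rnorm(n_knots, 0, wiggle * W / n_knots)) * 3
    x <- pmin(pmax(x, grid$xmin), grid$xmin + W)
  }
  # densify so rasterized corridors are contiguous
  dense <- stats::spline(ts, if (horizontal) y else x, n = n_knots * 20)$y
  tfine <- seq(0, 1, length.out = n_knots * 20)
  if (horizontal) cbind(grid$xmin + tfine * W, dense)
  else cbind(dense, grid$ymax - tfine * H)
}

circle_polygon <- function(cx, cy, radius, n = 24) {
  a <- seq(0, 2 * pi, length.out = n + 1)
  cbind(cx + radius * cos(a), cy + radius * sin(a))
}

rect_polygon <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))
}

#' Synthetic threat sources and protected areas
#'
#' Builds one source layer per threat factor: urban and farmland polygons
#' around high-disturbance / high-cropland patches, highway, railway and
#' river as random smooth polylines, port and tourism as point buffers.
#' Protected-area polygons are placed preferentially in low-disturbance
#' cells, reproducing the mismatch between protection and anthropogenic
#' invasion hotspots.
#'
#' @param env environmental stack.
#' @param lulc categorical land-cover `inv_raster`.
#' @param seed RNG seed (required).
#' @param n_pas number of protected-area polygons.
#' @return list with `vectors` (named list of `inv_vector`), `rasters`
#'   (named list of intensity `inv_raster`s in \[0,1\]), `pas`
#'   (`inv_vector` of polygons).
#' @export
make_threats_and_pas <- function(env, lulc, seed = NULL, n_pas = 12) {
  require_seed(seed)
  grid <- env[[1]]
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cellsize
  d <- scale01(scale01(env$DMSP$values) + scale01(env$RD$values) +
                 scale01(env$CP$values))
  with_seed(seed, {
    vectors <- list()
    # urban: rectangles around the largest high-disturbance patches
    cc <- connected_components8(lulc$values == 1)
    top <- order(cc$sizes, decreasing = TRUE)[seq_len(min(6, length(cc$sizes)))]
    urban_polys <- lapply(top, function(lab) {
      idx <- which(cc$labels == lab)
      i <- (idx - 1L) %% nr + 1L; j <- (idx - 1L) %/% nr + 1L
      rect_polygon(grid$xmin + (min(j) - 1) * cs, grid$ymax - max(i) * cs,
                   grid$xmin + max(j) * cs, grid$ymax - (min(i) - 1) * cs)
    })
    vectors$urban <- do.call(vec_polygon, urban_polys)
    # farmland: rectangles around high-cropland blocks
    cp_hi <- env$CP$values > stats::quantile(env$CP$values, 0.85)
    cf <- connected_components8(cp_hi)
    topf <- order(cf$sizes, decreasing = TRUE)[seq_len(min(6, length(cf$sizes)))]
    farm_polys <- lapply(topf, function(lab) {
      idx <- which(cf$labels == lab)
      i <- (idx - 1L) %% nr + 1L; j <- (idx - 1L) %/% nr + 1L
      rect_polygon(grid$xmin + (min(j) - 1) * cs, grid$ymax - max(i) * cs,
                   grid$xmin + max(j) * cs, grid$ymax - (min(i) - 1) * cs)
    })
    vectors$farmland <- do.call(vec_polygon, farm_polys)
    vectors$highway <- vec_lines(lapply(1:3, function(i) random_polyline(grid)))
    vectors$railway <- vec_lines(lapply(1:2, function(i) random_polyline(grid)))
    vectors$river <- vec_lines(lapply(1:3, function(i)
      random_polyline(grid, n_knots = 10, wiggle = 0.25)))
    # ports at high-nightlight cells, tourism anywhere
    pick_cells <- function(wts, n) {
      idx <- sample(length(wts), n, prob = wts)
      i <- (idx - 1L) %% nr + 1L; j <- (idx - 1L) %/% nr + 1L
      cbind(grid$xmin + (j - 0.5) * cs, grid$ymax - (i - 0.5) * cs)
    }
    ports <- pick_cells(as.vector(scale01(env$DMSP$values))^4 + 1e-6, 3)
    vectors$port <- do.call(vec_polygon, lapply(seq_len(nrow(ports)), function(i) {
      circle_polygon(ports[i, 1], ports[i, 2], 2 * cs)
    }))
    tour <- pick_cells(rep(1, nr * nc), 4)
    vectors$tourism <- do.call(vec_polygon, lapply(seq_len(nrow(tour)), function(i) {
      circle_polygon(tour[i, 1], tour[i, 2], 3 * cs)
    }))
    rasters <- lapply(vectors, rasterize, target = grid, mode = "presence")
    # protected areas preferentially in low-disturbance cells
    pa_centers <- pick_cells(as.vector((1 - d)^6) + 1e-9, n_pas)
    pa_polys <- lapply(seq_len(n_pas), function(i) {
      if (i %% 2 == 0) {
        circle_polygon(pa_centers[i, 1], pa_centers[i, 2],
                       stats::runif(1, 5, 14) * cs)
      } else {
        hw <- stats::runif(1, 5, 12) * cs; hh <- stats::runif(1, 5, 12) * cs
        rect_polygon(pa_centers[i, 1] - hw, pa_centers[i, 2] - hh,
                     pa_centers[i, 1] + hw, pa_centers[i, 2] + hh)
      }
    })
    pas <- do.call(vec_polygon, pa_polys)
    pas$attributes <- tibble::tibble(name = sprintf("PA%02d", seq_len(n_pas)))
    list(vectors = vectors, rasters = rasters, pas = pas)
  })
}

#' Complete synthetic landscape bundle
#'
#' The default fixture of the package: a 200 x 200 1-km grid with ten
#' environmental layers, a 7-class land-cover map, threat sources for all
#' seven factors, protected areas biased away from disturbance, Gaussian
#' species niches, a clustered observation-effort field, and occurrence
#' records sampled under that effort bias. Everything derives
#' deterministically from `seed`.
#'
#' @param shape grid shape (rows, cols).
#' @param n_species number of species (default 12).
#' @param records_per_species range of records per species.
#' @param bias_strength sampling-bias exponent (default 1).
#' @param spatial_range autocorrelation length in cells.
#' @param seed master RNG seed (default 20100898).
#' @return object of class `landscape_bundle`: list with `env`, `lulc`,
#'   `threats` (vectors + rasters), `pas`, `effort`, `niche`, `occurrences`.
#' @export
synthetic_landscape <- function(shape = c(200, 200), n_species = 12,
                                records_per_species = c(30, 300),
                                bias_strength = 0, spatial_range = 15,
                                seed = 20100898) {
  require_seed(seed)
  env <- make_env_stack(shape, seed = seed, spatial_range = spatial_range)
  lulc <- make_lulc(env)
  effort <- make_effort_field(env[[1]], seed = seed + 1)
  niche <- make_niche_params(env, n_species, seed = seed + 2)
  occ <- make_occurrences(env, niche, effort,
                          records_per_species = records_per_species,
                          bias_strength = bias_strength, seed = seed + 3)
  thr <- make_threats_and_pas(env, lulc, seed = seed + 4)
  structure(list(env = env, lulc = lulc,
                 threat_vectors = thr$vectors, threat_rasters = thr$rasters,
                 pas = thr$pas, effort = effort, niche = niche,
                 occurrences = occ, seed = seed),
            class = "landscape_bundle")
}

#' @export
print.landscape_bundle <- function(x, ...) {
  cat(sprintf(
    "<landscape_bundle> %dx%d grid, %d env layers, %d species, %d records, %d PAs\n",
    nrow(x$lulc$values), ncol(x$lulc$values), length(x$env),
    dplyr::n_distinct(x$occurrences$species), nrow(x$occurrences),
    length(x$pas$features)))
  invisible(x)
}

#' Write a landscape bundle to disk
#'
#' Writes the bundle in the same formats the pipeline consumes for real
#' data: ASCII grids for rasters, GeoJSON for vectors, CSV for tables.
#'
#' @param bundle a `landscape_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$env)) {
    write_raster(bundle$env[[nm]], file.path(dir, paste0("env_", nm, ".asc")))
  }
  write_raster(bundle$lulc, file.path(dir, "lulc.asc"))
  for (nm in names(bundle$threat_rasters)) {
    write_raster(bundle$threat_rasters[[nm]],
                 file.path(dir, paste0("threat_", nm, ".asc")))
  }
  write_geojson(bundle$pas, file.path(dir, "protected_areas.geojson"))
  utils::write.csv(bundle$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$niche, file.path(dir, "niche_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
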