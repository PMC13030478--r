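#' Default threat parameter table
#'
#' The seven anthropogenic threat factors with their maximum impact
#' distances (km), weights and decay types used by the degradation model.
#'
#' @return tibble with `threat`, `d_max_km`, `weight`, `decay`.
#' @export
threat_table <- function() {
  tibble::tribble(
    ~threat,    ~d_max_km, ~weight, ~decay,
    "highway",  2,         0.85,    "linear",
    "railway",  1,         0.65,    "linear",
    "urban",    4,         0.9,     "linear",
    "port",     1.5,       0.95,    "exponential",
    "farmland", 8,         0.7,     "linear",
    "river",    0.5,       0.5,     "exponential",
    "tourism",  3.5,       0.65,    "exponential"
  )
}

#' Default habitat scores and sensitivity matrix for the 7 LULC classes
#'
#' Land-use/land-cover codes: 1 high-intensity disturbance zones,
#' 2 degraded forestland, 3 shrubland, 4 wetland, 5 degraded grassland,
#' 6 transportation corridors, 7 primary vegetation areas. Habitat scores
#' H are high for wetland and primary vegetation and low for disturbance
#' zones and corridors. Sensitivities are literature-style defaults, fully
#' config-overridable; disturbance zones keep moderate (not near-zero)
#' sensitivity so that their proximity to urban and farmland sources shows
#' up as the highest degradation, the pattern the emulated study reports.
#'
#' @return `default_habitat_scores()`: tibble `lulc`, `label`, `habitat`.
#' @export
default_habitat_scores <- function() {
  tibble::tribble(
    ~lulc, ~label,                              ~habitat,
    1L, "high-intensity disturbance zones", 0.05,
    2L, "degraded forestland",              0.6,
    3L, "shrubland",                        0.7,
    4L, "wetland",                          1.0,
    5L, "degraded grassland",               0.5,
    6L, "transportation corridors",         0.1,
    7L, "primary vegetation areas",         0.95
  )
}

#' @rdname default_habitat_scores
#' @return `default_sensitivity()`: tibble `lulc` x threat columns in (0,1).
#' @export
default_sensitivity <- function() {
  tibble::tribble(
    ~lulc, ~highway, ~railway, ~urban, ~port, ~farmland, ~river, ~tourism,
    1L, 0.4, 0.3, 0.6, 0.4, 0.5, 0.2, 0.3,
    2L, 0.7, 0.6, 0.8, 0.5, 0.6, 0.3, 0.4,
    3L, 0.6, 0.5, 0.7, 0.4, 0.6, 0.3, 0.4,
    4L, 0.8, 0.7, 0.9, 0.8, 0.8, 0.4, 0.6,
    5L, 0.5, 0.4, 0.6, 0.4, 0.7, 0.3, 0.3,
    6L, 0.3, 0.3, 0.4, 0.2, 0.3, 0.2, 0.2,
    7L, 0.9, 0.8, 1.0, 0.7, 0.8, 0.5, 0.6
  )
}

#' Distance-decay factor of a threat
#'
#' Linear decay: 1 - d/d_max (0 beyond d_max). Exponential decay:
#' exp(-(2.99/d_max) d) inside d_max, 0 beyond; the constant 2.99
#' (about ln 20) makes the influence fall to about 5% at the maximum
#' impact distance.
#'
#' @param d distance(s) in km, >= 0.
#' @param d_max maximum impact distance in km.
#' @param decay `"linear"` or `"exponential"`.
#' @return decay factor(s) in \[0, 1\]; 1 at d = 0.
#' @export
decay_factor <- function(d, d_max, decay = c("linear", "exponential")) {
  decay <- match.arg(decay)
  if (any(d < 0)) stop("negative distance", call. = FALSE)
  if (d_max <= 0) stop("d_max must be positive", call. = FALSE)
  out <- if (decay == "linear") pmax(0, 1 - d / d_max) else
    exp(-(2.99 / d_max) * d)
  out[d > d_max] <- 0
  out
}

#' Distance-decayed influence field of one threat
#'
#' For every grid cell, the maximum over source cells y of r_y * i(d(x,y)),
#' where r_y is the source intensity in \[0,1\] and i the decay factor.
#' Taking the maximum (dominant nearby source) keeps the field, and hence
#' the degradation index, within \[0,1\] without renormalization.
#'
#' @param source `inv_raster` of threat intensity in \[0, 1\] (NA treated
#'   as no source).
#' @param d_max_km maximum impact distance (km).
#' @param decay `"linear"` or `"exponential"`.
#' @param cellsize_km ground size of one cell in km (default: the raster's
#'   cell size, i.e. map units are km).
#' @return `inv_raster` in \[0, 1\] on the source grid.
#' @export
threat_field <- function(source, d_max_km, decay = c("linear", "exponential"),
                         cellsize_km = source$cellsize) {
  decay <- match.arg(decay)
  v <- source$values
  fin <- v[is.finite(v)]
  if (length(fin) && (min(fin) < 0 || max(fin) > 1)) {
    stop("threat intensity must lie in [0, 1]", call. = FALSE)
  }
  src <- v
  src[!is.finite(src)] <- 0
  out <- const_like(source, 0)
  out$values <- threat_sweep(src, cellsize_km, d_max_km,
                             as.integer(decay == "exponential"))
  out
}

lookup_by_lulc <- function(lulc, table, column) {
  codes <- table$lulc
  v <- lulc$values
  fin <- is.finite(v)
  missing_codes <- setdiff(unique(as.integer(v[fin])), codes)
  if (length(missing_codes)) {
    stop("LULC code(s) absent from table: ",
         paste(missing_codes, collapse = ", "), call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[fin] <- table[[column]][match(as.integer(v[fin]), codes)]
  out
}

#' Habitat degradation index
#'
#' D(x) = sum_r (w_r / sum w) * field_r(x) * beta(x) * S_\{j(x), r\}, the
#' weight-normalized, sensitivity-scaled sum of distance-decayed threat
#' influences; by construction in \[0, 1\].
#'
#' @param fields named list of threat influence `inv_raster`s (from
#'   [threat_field()]); names must appear in `specs$threat`.
#' @param specs threat parameter tibble (see [threat_table()]); only
#'   `threat` and `weight` are used here.
#' @param sens sensitivity tibble: `lulc` column plus one column per threat
#'   (see [default_sensitivity()]).
#' @param lulc categorical `inv_raster` of land-cover codes.
#' @param accessibility optional `inv_raster` beta in \[0,1\] (default 1).
#' @return `inv_raster` of D in \[0, 1\].
#' @export
degradation <- function(fields, specs, sens, lulc, accessibility = NULL) {
  stopifnot(length(fields) >= 1, all(names(fields) %in% specs$threat))
  base <- fields[[1]]
  for (f in fields) stop_if_misaligned(f, base)
  stop_if_misaligned(lulc, base)
  w <- specs$weight[match(names(fields), specs$threat)]
  if (any(w <= 0)) stop("threat weights must be positive", call. = FALSE)
  wn <- w / sum(w)
  beta <- if (is.null(accessibility)) 1 else {
    stop_if_misaligned(accessibility, base)
    accessibility$values
  }
  acc <- matrix(0, nrow(base$values), ncol(base$values))
  for (i in seq_along(fields)) {
    S <- lookup_by_lulc(lulc, sens, names(fields)[i])
    acc <- acc + wn[i] * fields[[i]]$values * S
  }
  acc <- acc * beta
  acc[!is.finite(lulc$values)] <- NA_real_
  out <- const_like(base, 0)
  out$values <- acc
  out
}

#' Habitat quality index
#'
#' Q(x) = H_\{j(x)\} * (1 - D(x)^z / (D(x)^z + K^z)): the per-LULC habitat
#' score attenuated by degradation through a half-saturation response with
#' constant K and exponent z (default 2.5). At D = K quality is halved;
#' at D = 0, Q = H; H = 0 forces Q = 0.
#'
#' @param D degradation `inv_raster` (from [degradation()]).
#' @param scores habitat-score tibble (`lulc`, `habitat`), see
#'   [default_habitat_scores()].
#' @param lulc categorical `inv_raster`.
#' @param K half-saturation constant (> 0), see [calibrate_k()].
#' @param z half-saturation exponent (default 2.5).
#' @return `inv_raster` of Q in \[0, 1\].
#' @export
quality <- function(D, scores, lulc, K, z = 2.5) {
  if (K <= 0) stop("K must be positive", call. = FALSE)
  stop_if_misaligned(D, lulc)
  H <- lookup_by_lulc(lulc, scores, "habitat")
  d <- D$values
  q <- H * (1 - d^z / (d^z + K^z))
  out <- const_like(D, 0)
  out$values <- q
  attr(out, "K") <- K
  attr(out, "z") <- z
  out
}

#' Calibrate the half-saturation constant K
#'
#' Iterates the half-of-maximum rule K <- max(D)/2 from `k_init` until the
#' update changes K by less than 1e-6 (one application suffices when D does
#' not depend on K; the loop guards recomputation rounds). An all-zero D
#' leaves K at `k_init` with a warning.
#'
#' @param D degradation `inv_raster`.
#' @param k_init initial K (default 0.05).
#' @param max_rounds safety cap on update rounds.
#' @return K, with attribute `trace` (the K value after each round).
#' @export
calibrate_k <- function(D, k_init = 0.05, max_rounds = 25) {
  dmax <- max(D$values, na.rm = TRUE)
  if (!is.finite(dmax) || dmax <= 0) {
    warning("degradation is zero everywhere; K kept at k_init")
    return(structure(k_init, trace = k_init))
  }
  K <- k_init
  trace <- K
  for (i in seq_len(max_rounds)) {
    K_new <- dmax / 2
    trace <- c(trace, K_new)
    if (abs(K_new - K) < 1e-6) { K <- K_new; break }
    K <- K_new
  }
  structure(K, trace = trace)
}

#' Degradation tiers and high-vulnerability mask
#'
#' Classifies D into five tiers (low, relatively low, medium, relatively
#' high, high) at the given ascending thresholds using the shared
#' upper-closed boundary convention, and returns the high-vulnerability
#' mask defined directly as D >= `vuln_threshold` (so a cell exactly at the
#' vulnerability threshold is high-vulnerability).
#'
#' @param D degradation `inv_raster`.
#' @param thresholds four ascending tier boundaries
#'   (default 0.17, 0.31, 0.42, 0.55).
#' @param vuln_threshold vulnerability cut-off (default 0.31, the lower edge
#'   of the medium tier).
#' @return list with `tiers` (`zone_classification`), `high_vulnerability`
#'   (binary `inv_raster`).
#' @export
classify_degradation <- function(D, thresholds = c(0.17, 0.31, 0.42, 0.55),
                                 vuln_threshold = 0.31) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be ascending", call. = FALSE)
  }
  tiers <- classify_zones(D, thresholds,
                          labels = c("low", "relatively low", "medium",
                                     "relatively high", "high"))
  mask <- map_raster(D, function(v) {
    b <- (v >= vuln_threshold) + 0
    b[!is.finite(v)] <- NA_real_
    b
  })
  attr(mask, "threshold") <- vuln_threshold
  list(tiers = tiers, high_vulnerability = mask)
}

#' Correlation of each threat field with degradation
#'
#' Pearson correlation (and its test p-value) between each threat's
#' influence field and D over a seeded sample of valid cells.
#'
#' @param D degradation `inv_raster`.
#' @param fields named list of threat influence rasters.
#' @param n_sample maximum cells sampled (default 10000).
#' @param seed RNG seed for the cell sample.
#' @return tibble with `threat`, `r`, `p`, `n` (r is NA with a note when a
#'   field has zero variance).
#' @export
threat_correlations <- function(D, fields, n_sample = 10000, seed = 1) {
  d <- as.vector(D$values)
  valid <- which(is.finite(d))
  if (length(valid) < 3) stop("need at least 3 valid cells", call. = FALSE)
  idx <- if (length(valid) > n_sample) {
    with_seed(seed, sample(valid, n_sample))
  } else valid
  dplyr::bind_rows(lapply(names(fields), function(nm) {
    f <- as.vector(fields[[nm]]$values)[idx]
    dd <- d[idx]
    ok <- is.finite(f) & is.finite(dd)
    if (stats::sd(f[ok]) == 0 || stats::sd(dd[ok]) == 0) {
      return(tibble::tibble(threat = nm, r = NA_real_, p = NA_real_,
                            n = sum(ok), note = "zero variance"))
    }
    ct <- stats::cor.test(f[ok], dd[ok])
    tibble::tibble(threat = nm, r = unname(ct$estimate), p = ct$p.value,
                   n = sum(ok), note = NA_character_)
  }))
}
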