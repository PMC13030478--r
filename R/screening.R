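#' Spatially thin occurrences and drop data-poor species
#'
#' Two-step screening of raw occurrence records: (1) retain a single record
#' per species within each `cell_km` x `cell_km` thinning cell, keeping the
#' first record after a deterministic sort by (species, y, x); (2) exclude
#' species left with fewer than `min_records` records. Thinning cells are
#' anchored at `origin` and follow the package's half-open ownership
#' convention.
#'
#' @param occ tibble with columns `species`, `x`, `y` (map units = km on the
#'   nominal grid).
#' @param cell_km thinning cell size in km (default 5).
#' @param min_records minimum records a species needs to be retained
#'   (default 5).
#' @param origin x/y anchor of the thinning lattice.
#' @return tibble of retained records with attributes `stage = "retained"`
#'   and `screen_log` (a tibble of per-stage record and species counts).
#' @export
thin_and_filter <- function(occ, cell_km = 5, min_records = 5,
                            origin = c(0, 0)) {
  occ <- tibble::as_tibble(occ)
  stopifnot(all(c("species", "x", "y") %in% names(occ)))
  if (!nrow(occ)) {
    warning("empty occurrence set")
    out <- occ
    attr(out, "stage") <- "retained"
    attr(out, "screen_log") <- tibble::tibble(
      stage = c("raw", "thinned", "retained"),
      n_records = 0L, n_species = 0L
    )
    return(out)
  }
  thinned <- occ |>
    dplyr::mutate(
      .cx = floor((.data$x - origin[1]) / cell_km),
      .cy = floor((origin[2] - .data$y) / cell_km)
    ) |>
    dplyr::arrange(.data$species, .data$y, .data$x) |>
    dplyr::distinct(.data$species, .data$.cx, .data$.cy, .keep_all = TRUE) |>
    dplyr::select(-".cx", -".cy")
  retained <- thinned |>
    dplyr::group_by(.data$species) |>
    dplyr::filter(dplyr::n() >= min_records) |>
    dplyr::ungroup()
  log <- tibble::tibble(
    stage = c("raw", "thinned", "retained"),
    n_records = c(nrow(occ), nrow(thinned), nrow(retained)),
    n_species = c(dplyr::n_distinct(occ$species),
                  dplyr::n_distinct(thinned$species),
                  dplyr::n_distinct(retained$species))
  )
  attr(retained, "stage") <- "retained"
  attr(retained, "screen_log") <- log
  retained
}

#' Collinearity screening of environmental layers
#'
#' Iteratively removes predictors until all pairwise |r| <= `r_max` and all
#' variance-inflation factors are <= `vif_max`. At each round the variable
#' with the largest VIF is dropped (ties broken by larger mean absolute
#' correlation, then lexicographically). All-constant layers are removed
#' first with an explicit reason.
#'
#' @param stack named list of aligned `inv_raster`s, or a data frame of
#'   variable values (rows = cells/points).
#' @param r_max pairwise absolute-correlation ceiling (default 0.8).
#' @param vif_max VIF ceiling (default 5).
#' @return list with `retained` (character), `report` (tibble: variable,
#'   removed, step, reason, vif at decision time), `vif` (final VIFs).
#' @export
screen_collinearity <- function(stack, r_max = 0.8, vif_max = 5) {
  df <- if (is.data.frame(stack)) {
    tibble::as_tibble(stack)
  } else {
    base <- stack[[1]]
    for (l in stack) stop_if_misaligned(l, base)
    tibble::as_tibble(lapply(stack, function(l) as.vector(l$values)))
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (ncol(df) < 2) stop("need at least two layers", call. = FALSE)
  if (!nrow(df)) stop("no jointly finite cells", call. = FALSE)
  vars <- names(df)
  report <- tibble::tibble(variable = character(), step = integer(),
                           reason = character(), vif = numeric())
  step <- 0L
  # constant layers can never be used as predictors
  for (v in vars[vapply(df, function(x) stats::sd(x) == 0, TRUE)]) {
    step <- step + 1L
    report <- dplyr::bind_rows(report, tibble::tibble(
      variable = v, step = step, reason = "constant layer", vif = NA_real_))
    vars <- setdiff(vars, v)
  }
  vif_of <- function(d) {
    vapply(names(d), function(v) {
      others <- setdiff(names(d), v)
      if (!length(others)) return(1)
      fit <- stats::lm.fit(cbind(1, as.matrix(d[others])), d[[v]])
      r2 <- 1 - sum(fit$residuals^2) / sum((d[[v]] - mean(d[[v]]))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  }
  repeat {
    if (length(vars) < 2) break
    d <- df[vars]
    cm <- abs(stats::cor(d))
    diag(cm) <- 0
    vif <- vif_of(d)
    if (max(cm) <= r_max && max(vif) <= vif_max) break
    worst <- vif == max(vif)
    if (sum(worst) > 1) {
      mr <- rowMeans(cm)[worst]
      cand <- names(mr)[mr == max(mr)]
      drop <- sort(cand)[1]
    } else {
      drop <- names(vif)[worst]
    }
    step <- step + 1L
    reason <- if (max(vif) > vif_max) {
      sprintf("VIF %.3g > %g", vif[[drop]], vif_max)
    } else {
      sprintf("|r| %.3g > %g", max(cm), r_max)
    }
    report <- dplyr::bind_rows(report, tibble::tibble(
      variable = drop, step = step, reason = reason, vif = vif[[drop]]))
    vars <- setdiff(vars, drop)
  }
  final_vif <- if (length(vars) >= 2) vif_of(df[vars]) else
    stats::setNames(rep(1, length(vars)), vars)
  report$removed <- TRUE
  list(retained = vars,
       report = report[, c("variable", "removed", "step", "reason", "vif")],
       vif = final_vif)
}

#' Target-group sampling-effort (bias) surface
#'
#' Gaussian kernel density of all pooled occurrence records on the analysis
#' grid, floored at a small epsilon and normalized to sum 1 over valid
#' cells, for use as a background-sampling bias file.
#'
#' @param occ tibble with `x`, `y` (all species pooled).
#' @param grid `inv_raster` defining the analysis grid (its nodata cells are
#'   excluded).
#' @param bandwidth Gaussian kernel standard deviation in cells.
#' @param eps positive floor guaranteeing a strictly positive surface.
#' @return `inv_raster` summing to 1 over valid cells.
#' @export
build_bias_surface <- function(occ, grid, bandwidth = 5, eps = 1e-8) {
  if (!nrow(occ)) stop("no occurrence records to build a bias surface from",
                       call. = FALSE)
  rc <- cell_of(grid, occ$x, occ$y)
  ok <- !is.na(rc$row)
  counts <- matrix(0, nrow(grid$values), ncol(grid$values))
  if (any(ok)) {
    t <- table(factor(rc$row[ok], levels = seq_len(nrow(counts))),
               factor(rc$col[ok], levels = seq_len(ncol(counts))))
    counts <- counts + unclass(t)
  }
  dens <- gauss_smooth(counts, bandwidth) + eps
  dens[!is.finite(grid$values)] <- NA_real_
  dens <- dens / sum(dens, na.rm = TRUE)
  out <- const_like(grid, 0)
  out$values <- dens
  out
}

#' Sample background points from a bias surface
#'
#' Draws `n` cells with replacement with probability proportional to the
#' bias surface, returning their center coordinates.
#'
#' @param bias probability `inv_raster` (e.g. from [build_bias_surface()]).
#' @param n number of background points (default 10000).
#' @param seed RNG seed (required for reproducibility).
#' @return tibble with `row`, `col`, `x`, `y`.
#' @export
sample_background <- function(bias, n = 10000, seed = NULL) {
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  require_seed(seed)
  p <- as.vector(bias$values)
  valid <- which(is.finite(p) & p > 0)
  idx <- with_seed(seed, valid[sample.int(length(valid), n, replace = TRUE,
                                          prob = p[valid])])
  nr <- nrow(bias$values)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  tibble::tibble(
    row = row, col = col,
    x = bias$xmin + (col - 0.5) * bias$cellsize,
    y = bias$ymax - (row - 0.5) * bias$cellsize
  )
}
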