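#' Stack per-species binary suitability maps into a richness raster
#'
#' Cell-wise integer sum of aligned binary maps; a cell that is nodata in any
#' layer is nodata in the stack (the count of such cells is recorded in the
#' `n_nodata` attribute).
#'
#' @param maps list of binary `inv_raster`s on a common grid.
#' @return an `inv_raster` of species counts, with attribute `n_species`.
#' @export
stack_binary <- function(maps) {
  stopifnot(length(maps) >= 1)
  base <- maps[[1]]
  acc <- matrix(0, nrow(base$values), ncol(base$values))
  bad <- matrix(FALSE, nrow(base$values), ncol(base$values))
  for (m in maps) {
    stop_if_misaligned(m, base)
    v <- m$values
    if (length(v[is.finite(v)]) && !all(v[is.finite(v)] %in% c(0, 1))) {
      stop("stack_binary expects binary maps", call. = FALSE)
    }
    bad <- bad | !is.finite(v)
    v[!is.finite(v)] <- 0
    acc <- acc + v
  }
  acc[bad] <- NA_real_
  out <- const_like(base, 0)
  out$values <- acc
  attr(out, "n_species") <- length(maps)
  attr(out, "n_nodata") <- sum(bad)
  out
}

#' Jenks natural-breaks classification
#'
#' Globally optimal 1-D classification into `k` contiguous classes minimizing
#' the within-class sum of squared deviations, via an exact dynamic program
#' on weighted distinct values. When more than `sample_max` finite values are
#' supplied, a seeded random sample is classified instead (the spec-scale
#' practice of computing breaks on a large random point sample).
#'
#' @param values numeric vector (non-finite values dropped).
#' @param k number of classes (default 5).
#' @param sample_max maximum number of values fed to the dynamic program.
#' @param seed seed used if sampling is needed.
#' @return numeric vector of k-1 class maxima (upper bounds of classes
#'   1..k-1), with attribute `ssw` (total within-class sum of squares of the
#'   classified sample) and `k`.
#' @export
jenks_breaks <- function(values, k = 5, sample_max = 10000, seed = 1) {
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values to classify", call. = FALSE)
  if (length(v) > sample_max) {
    v <- with_seed(seed, sample(v, sample_max))
  }
  tab <- table(v)
  u <- as.numeric(names(tab))
  w <- as.numeric(tab)
  if (length(u) < k) {
    warning(sprintf("only %d distinct values; reducing k from %d", length(u), k))
    k <- length(u)
  }
  if (k == 1) {
    br <- numeric(0)
  } else {
    idx <- jenks_dp(u, w, as.integer(k))
    br <- u[idx + 1L]
  }
  structure(br, ssw = jenks_dp_ssw(u, w, as.integer(k)), k = k)
}

#' Classify a raster into ordered zones
#'
#' Applies ascending breaks with the package-wide boundary convention:
#' a value equal to a break belongs to the lower zone (classes are
#' upper-closed). Values beyond the break range fall in the extreme zones.
#'
#' @param raster continuous `inv_raster`.
#' @param breaks ascending numeric vector of k-1 class maxima (e.g. from
#'   [jenks_breaks()]).
#' @param labels optional character vector of k zone labels (low to high).
#' @return a `zone_classification`: list with `zones` (categorical
#'   `inv_raster`, codes 1..k low to high), `breaks`, `labels`.
#' @export
classify_zones <- function(raster, breaks,
                           labels = c("low", "relatively low", "medium",
                                      "relatively high", "high")) {
  breaks <- as.numeric(breaks)
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing", call. = FALSE)
  }
  k <- length(breaks) + 1L
  if (length(labels) != k) labels <- paste("zone", seq_len(k))
  v <- raster$values
  z <- matrix(NA_real_, nrow(v), ncol(v))
  fin <- is.finite(v)
  # value <= break_i -> zone i (first matching); above all breaks -> k
  z[fin] <- findInterval(v[fin], breaks, left.open = TRUE) + 1L
  zr <- inv_raster(z, xmin = raster$xmin, ymax = raster$ymax,
                   cellsize = raster$cellsize, crs = raster$crs,
                   nodata = raster$nodata, kind = "categorical",
                   codes = seq_len(k))
  structure(list(zones = zr, breaks = breaks, labels = labels, k = k),
            class = "zone_classification")
}

#' @export
print.zone_classification <- function(x, ...) {
  cat(sprintf("<zone_classification> %d zones; breaks: %s\n", x$k,
              paste(signif(x$breaks, 4), collapse = ", ")))
  invisible(x)
}

#' High-suitability mask from a five-zone richness classification
#'
#' Cells in the top three zones (medium, relatively high, high richness;
#' codes 3-5) form the high-suitability habitat mask.
#'
#' @param zc a 5-zone `zone_classification`.
#' @return binary `inv_raster`.
#' @export
high_suitability_mask <- function(zc) {
  stopifnot(inherits(zc, "zone_classification"))
  if (zc$k != 5) stop("a 5-zone classification is required", call. = FALSE)
  map_raster(zc$zones, function(v) {
    out <- (v >= 3) + 0
    out[!is.finite(v)] <- NA_real_
    out
  }, kind = "continuous", codes = NULL)
}

#' Zone area tally
#'
#' @param zc a `zone_classification`.
#' @param cell_area nominal cell area in km².
#' @return tibble with `zone`, `label`, `n_cells`, `area_km2`.
#' @export
zone_areas <- function(zc, cell_area = 1) {
  v <- zc$zones$values
  counts <- vapply(seq_len(zc$k), function(z) sum(v == z, na.rm = TRUE), 0)
  tibble::tibble(zone = seq_len(zc$k), label = zc$labels, n_cells = counts,
                 area_km2 = counts * cell_area)
}
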