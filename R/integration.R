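#' Core invasion habitat: intersection of suitability and vulnerability
#'
#' Produces the 4-category priority map: 3 = core (both masks), 1 =
#' high-suitability only, 2 = high-vulnerability only (the secondary
#' priority categories), 0 = neither.
#'
#' @param high_suit binary `inv_raster` (high-suitability habitats).
#' @param high_vuln binary `inv_raster` (high-vulnerability habitats).
#' @return object of class `priority_map`: list with `map` (categorical
#'   `inv_raster`, codes 0-3) and `areas` (tibble of cell counts).
#' @export
core_habitat <- function(high_suit, high_vuln) {
  stop_if_misaligned(high_suit, high_vuln)
  s <- high_suit$values; v <- high_vuln$values
  cat_ <- ifelse(s == 1 & v == 1, 3, ifelse(s == 1, 1, ifelse(v == 1, 2, 0)))
  cat_[!is.finite(s) | !is.finite(v)] <- NA_real_
  m <- inv_raster(cat_, xmin = high_suit$xmin, ymax = high_suit$ymax,
                  cellsize = high_suit$cellsize, crs = high_suit$crs,
                  nodata = high_suit$nodata, kind = "categorical",
                  codes = 0:3)
  areas <- tibble::tibble(
    category = c("none", "suitability-only", "vulnerability-only", "core"),
    code = 0:3,
    n_cells = vapply(0:3, function(k) sum(cat_ == k, na.rm = TRUE), 0)
  )
  structure(list(map = m, areas = areas), class = "priority_map")
}

#' @export
print.priority_map <- function(x, ...) {
  cat("<priority_map>\n"); print(x$areas); invisible(x)
}

category_mask <- function(priority, code) {
  map_raster(priority$map, function(v) {
    b <- (v == code) + 0
    b[!is.finite(v)] <- NA_real_
    b
  }, kind = "continuous", codes = NULL)
}

#' Protected-area gap analysis of core habitat
#'
#' Rasterizes the protected-area polygons (cell-center membership), splits
#' the core habitat into its protected part and the conservation gap
#' outside the network, and reports areas, percentages, and the land-cover
#' composition of the core.
#'
#' @param priority a `priority_map` from [core_habitat()], or a binary core
#'   mask `inv_raster`.
#' @param pas protected areas: an `inv_vector` of polygons or an aligned
#'   binary `inv_raster`.
#' @param cell_area nominal cell area in km² (default 1).
#' @param lulc optional categorical `inv_raster` for core composition.
#' @return object of class `gap_report`: list with `summary` (tibble:
#'   core/protected/gap areas and percentages), `composition` (tibble or
#'   NULL), and the `protected`/`gap` masks.
#' @export
gap_analysis <- function(priority, pas, cell_area = 1, lulc = NULL) {
  core <- if (inherits(priority, "priority_map")) {
    category_mask(priority, 3)
  } else priority
  pa_mask <- if (inherits(pas, "inv_vector")) {
    if (!length(pas$features)) {
      warning("empty protected-area layer: gap is 100% of core")
    }
    rasterize(pas, core, mode = "presence")
  } else {
    stop_if_misaligned(pas, core)
    pas
  }
  c_v <- core$values; p_v <- pa_mask$values
  prot <- map_raster(core, function(v) {
    b <- (v == 1 & p_v == 1) + 0
    b[!is.finite(v)] <- NA_real_
    b
  })
  gap <- map_raster(core, function(v) {
    b <- (v == 1 & p_v != 1) + 0
    b[!is.finite(v)] <- NA_real_
    b
  })
  a_core <- area_of(core, cell_area)
  a_prot <- area_of(prot, cell_area)
  a_gap <- area_of(gap, cell_area)
  summary <- tibble::tibble(
    quantity = c("core", "protected core", "conservation gap"),
    area_km2 = c(a_core, a_prot, a_gap),
    pct_of_core = if (a_core > 0) 100 * c(a_core, a_prot, a_gap) / a_core
                  else c(NA_real_, NA_real_, NA_real_)
  )
  comp <- if (!is.null(lulc) && a_core > 0) composition(core, lulc) else NULL
  if (a_core == 0) warning("core habitat is empty; composition skipped")
  structure(list(summary = summary, composition = comp,
                 protected = prot, gap = gap),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report>\n"); print(x$summary)
  if (!is.null(x$composition)) { cat("Core composition:\n"); print(x$composition) }
  invisible(x)
}

#' @export
glance.gap_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    core_km2 = s$area_km2[s$quantity == "core"],
    protected_km2 = s$area_km2[s$quantity == "protected core"],
    gap_km2 = s$area_km2[s$quantity == "conservation gap"],
    protected_pct = s$pct_of_core[s$quantity == "protected core"],
    gap_pct = s$pct_of_core[s$quantity == "conservation gap"]
  )
}

#' Per-class composition of a mask
#'
#' Fraction of the mask's 1-cells falling in each class of a categorical
#' raster; proportions sum to 1.
#'
#' @param mask binary `inv_raster`.
#' @param classes categorical `inv_raster` (e.g. land cover), aligned.
#' @return tibble with `class`, `n_cells`, `proportion`.
#' @export
composition <- function(mask, classes) {
  stop_if_misaligned(mask, classes)
  sel <- mask$values == 1 & is.finite(classes$values)
  if (!any(sel, na.rm = TRUE)) stop("empty mask", call. = FALSE)
  cl <- as.integer(classes$values[which(sel)])
  tab <- table(cl)
  tibble::tibble(
    class = as.integer(names(tab)),
    n_cells = as.integer(tab),
    proportion = as.numeric(tab) / sum(tab)
  )
}

#' Pathway risk and dominance analysis
#'
#' For the linear dispersal pathways (highway, railway, river), computes
#' each pathway's per-cell weighted risk contribution
#' (w_r / sum w) * field_r(x) * S_\{j(x), r\}, its mean over the pathway's
#' corridor footprint, the per-cell dominant pathway (ties resolved by the
#' order of `fields`, highway before railway before river), and hotspots --
#' cells in the top Jenks class of each pathway's positive contribution --
#' with 8-connected contiguity statistics.
#'
#' @param fields named list of pathway threat-influence rasters (order =
#'   tie-break priority).
#' @param specs threat parameter tibble with `threat`, `weight`.
#' @param sens sensitivity tibble (`lulc` x threat columns).
#' @param lulc categorical land-cover `inv_raster`.
#' @param corridor_masks optional named list of binary corridor footprints;
#'   default: cells where the pathway's field is positive.
#' @param k_hotspot Jenks classes used for the hotspot rule (top class of
#'   `k_hotspot`).
#' @param cell_area nominal cell area (km²).
#' @param seed passed to Jenks sampling.
#' @return object of class `pathway_risk`: list with `summary` (tibble:
#'   pathway, mean corridor risk, hotspot area, largest contiguous hotspot,
#'   dominance fraction), `dominant` (categorical raster; 0 = no pathway).
#' @export
pathway_dominance <- function(fields, specs, sens, lulc,
                              corridor_masks = NULL, k_hotspot = 5,
                              cell_area = 1, seed = 1) {
  stopifnot(length(fields) >= 1)
  base <- fields[[1]]
  w <- specs$weight[match(names(fields), specs$threat)]
  wn <- w / sum(specs$weight[match(names(fields), specs$threat)])
  contrib <- lapply(seq_along(fields), function(i) {
    S <- lookup_by_lulc(lulc, sens, names(fields)[i])
    wn[i] * fields[[i]]$values * S
  })
  names(contrib) <- names(fields)
  stacked <- array(unlist(contrib), dim = c(dim(base$values), length(fields)))
  any_pos <- apply(stacked > 0, c(1, 2), any)
  if (!any(any_pos, na.rm = TRUE)) {
    warning("all pathway fields are zero; dominance undefined")
    return(structure(list(summary = tibble::tibble(), dominant = NULL,
                          contributions = contrib), class = "pathway_risk"))
  }
  # argmax with first-listed priority on ties: iterate in reverse so the
  # earliest pathway overwrites on >=
  dom <- matrix(0, nrow(base$values), ncol(base$values))
  best <- matrix(-Inf, nrow(base$values), ncol(base$values))
  for (i in rev(seq_along(fields))) {
    ci <- contrib[[i]]
    upd <- !is.na(ci) & ci > 0 & ci >= best
    dom[upd] <- i
    best[upd] <- ci[upd]
  }
  dom[!is.finite(lulc$values)] <- NA_real_
  n_covered <- sum(dom > 0, na.rm = TRUE)
  rows <- lapply(seq_along(fields), function(i) {
    ci <- contrib[[i]]
    corridor <- if (!is.null(corridor_masks)) {
      corridor_masks[[names(fields)[i]]]$values == 1
    } else fields[[i]]$values > 0
    mean_risk <- if (any(corridor, na.rm = TRUE)) {
      mean(ci[which(corridor)], na.rm = TRUE)
    } else NA_real_
    pos <- ci[is.finite(ci) & ci > 0]
    hot_mask <- matrix(FALSE, nrow(ci), ncol(ci))
    hot_area <- 0; largest <- 0
    if (length(unique(pos)) >= 2) {
      kb <- jenks_breaks(pos, k = min(k_hotspot, length(unique(pos))),
                         seed = seed)
      cut <- if (length(kb)) kb[length(kb)] else max(pos)
      hot_mask <- !is.na(ci) & ci > cut & corridor
      hot_area <- sum(hot_mask, na.rm = TRUE) * cell_area
      if (any(hot_mask)) {
        cc <- connected_components8(hot_mask)
        largest <- max(cc$sizes) * cell_area
      }
    }
    tibble::tibble(
      pathway = names(fields)[i],
      weight = w[i],
      mean_corridor_risk = mean_risk,
      hotspot_area_km2 = hot_area,
      largest_hotspot_km2 = largest,
      dominance_fraction = sum(dom == i, na.rm = TRUE) / max(n_covered, 1)
    )
  })
  dom_r <- inv_raster(dom, xmin = base$xmin, ymax = base$ymax,
                      cellsize = base$cellsize, crs = base$crs,
                      nodata = base$nodata, kind = "categorical",
                      codes = 0:length(fields))
  structure(list(summary = dplyr::bind_rows(rows), dominant = dom_r,
                 contributions = contrib), class = "pathway_risk")
}

#' @export
print.pathway_risk <- function(x, ...) {
  cat("<pathway_risk>\n"); print(x$summary); invisible(x)
}

#' @export
tidy.pathway_risk <- function(x, ...) x$summary
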