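#' Gridded raster layers
#'
#' `inv_raster()` builds the light-weight raster container used throughout the
#' package: a numeric matrix with an affine georeference (cell-center
#' registration, row 1 = northernmost row), a CRS identifier, a nodata
#' sentinel used on disk, and a `kind` flag distinguishing continuous fields
#' from integer-coded categorical maps.
#'
#' Grid convention, used everywhere in the package: cells are referenced by
#' their centers; cell ownership is half-open, so a point lying exactly on a
#' shared edge belongs to the cell to the south/east of the edge.
#'
#' @param values numeric matrix; `NA` marks nodata cells internally.
#' @param xmin,ymax map coordinates of the grid's west edge / north edge.
#' @param cellsize cell size in map units (must be > 0).
#' @param crs coordinate reference identifier (default WGS84).
#' @param nodata sentinel written to / read from disk files.
#' @param kind `"continuous"` or `"categorical"`.
#' @param codes for categorical grids, the integer code list allowed.
#' @return An object of class `inv_raster`.
#' @export
inv_raster <- function(values, xmin = 0, ymax = nrow(values), cellsize = 1,
                       crs = "EPSG:4326", nodata = -9999,
                       kind = c("continuous", "categorical"), codes = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(nrow(values) >= 1, ncol(values) >= 1)
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0) {
    stop("`cellsize` must be a single strictly positive number", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (kind == "categorical") {
    v <- values[is.finite(values)]
    if (any(v != round(v))) {
      stop("categorical raster contains non-integer codes", call. = FALSE)
    }
    if (is.null(codes)) codes <- sort(unique(as.integer(v)))
    if (length(setdiff(unique(as.integer(v)), codes)) > 0) {
      stop("categorical raster contains codes outside the declared code list",
           call. = FALSE)
    }
    if (nodata %in% codes) {
      stop("nodata sentinel collides with a declared category code", call. = FALSE)
    }
  }
  structure(
    list(values = values, xmin = xmin, ymax = ymax, cellsize = cellsize,
         crs = crs, nodata = nodata, kind = kind, codes = codes),
    class = "inv_raster"
  )
}

#' @export
print.inv_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<inv_raster> %d x %d cells of %g map units (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$kind, x$crs))
  if (length(v)) {
    cat(sprintf("  range [%g, %g], %d nodata cells\n", min(v), max(v),
                sum(!is.finite(x$values))))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

#' @export
dim.inv_raster <- function(x) dim(x$values)

n_valid <- function(r) sum(is.finite(r$values))

same_grid <- function(a, b, tol = 1e-9) {
  all(dim(a$values) == dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$cellsize - b$cellsize) < tol && identical(a$crs, b$crs)
}

stop_if_misaligned <- function(a, b) {
  if (!same_grid(a, b)) stop("rasters are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

#' Cell-center coordinates and point-to-cell lookup
#'
#' `cell_centers()` returns a tibble of all cell centers; `cell_of()` maps
#' points to (row, col) indices under the half-open ownership convention
#' (a point on a shared edge belongs to the south/east cell).
#'
#' @param r an `inv_raster`.
#' @return `cell_centers()`: tibble with `row`, `col`, `x`, `y`, `value`.
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = r$xmin + (rep(seq_len(nc), each = nr) - 0.5) * r$cellsize,
    y = r$ymax - (rep(seq_len(nr), times = nc) - 0.5) * r$cellsize,
    value = as.vector(r$values)
  )
}

#' @param x,y point coordinates in the grid CRS.
#' @rdname cell_centers
#' @return `cell_of()`: tibble with `row`, `col` (`NA` outside the grid).
#' @export
cell_of <- function(r, x, y) {
  col <- floor((x - r$xmin) / r$cellsize) + 1L
  row <- floor((r$ymax - y) / r$cellsize) + 1L
  # half-open: a point on the east/south boundary of the full grid is outside
  bad <- col < 1L | col > ncol(r$values) | row < 1L | row > nrow(r$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  tibble::tibble(row = row, col = col)
}

#' Read and write ESRI ASCII grids
#'
#' Rasters are exchanged as single-band ESRI ASCII grids (`.asc`) with a
#' plain-text `.prj` sidecar carrying the CRS identifier. The reader refuses
#' files without a resolvable CRS rather than silently assuming one.
#'
#' @param path file path of the `.asc` grid.
#' @param crs CRS identifier; if `NULL`, read from the `.prj` sidecar.
#' @param kind `"continuous"` or `"categorical"`; if `NULL`, taken from the
#'   sidecar metadata when present, else continuous.
#' @return `read_raster()`: an `inv_raster`.
#' @export
read_raster <- function(path, crs = NULL, kind = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not a single-band ESRI ASCII grid: ", path, call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  n_hdr <- 5L + !is.null(hdr$nodata_value)
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("grid body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  meta <- if (file.exists(prj)) readLines(prj, warn = FALSE) else character()
  if (is.null(crs)) {
    if (!length(meta)) {
      stop("no CRS: supply `crs` or provide a .prj sidecar for ", path,
           call. = FALSE)
    }
    crs <- trimws(meta[1])
  }
  if (is.null(kind)) {
    kind <- if (length(meta) >= 2 && trimws(meta[2]) == "categorical") {
      "categorical"
    } else "continuous"
  }
  inv_raster(m, xmin = hdr$xllcorner,
             ymax = hdr$yllcorner + nr * hdr$cellsize,
             cellsize = hdr$cellsize, crs = crs, nodata = nodata, kind = kind)
}

#' @param r an `inv_raster` to write.
#' @param digits significant digits written for continuous grids.
#' @rdname read_raster
#' @return `write_raster()`: `path`, invisibly.
#' @export
write_raster <- function(r, path, digits = 10) {
  m <- r$values
  m[!is.finite(m)] <- r$nodata
  hdr <- c(
    sprintf("NCOLS %d", ncol(m)),
    sprintf("NROWS %d", nrow(m)),
    sprintf("XLLCORNER %.10g", r$xmin),
    sprintf("YLLCORNER %.10g", r$ymax - nrow(m) * r$cellsize),
    sprintf("CELLSIZE %.10g", r$cellsize),
    sprintf("NODATA_VALUE %.10g", r$nodata)
  )
  fmt <- if (r$kind == "categorical") "%d" else paste0("%.", digits, "g")
  body <- apply(m, 1, function(row) {
    if (r$kind == "categorical") row <- as.integer(round(row))
    paste(sprintf(fmt, row), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  writeLines(c(r$crs, r$kind), paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}

#' Align raster layers onto a target grid
#'
#' Resamples each layer onto the grid of `target`: continuous layers
#' bilinearly, categorical layers by nearest neighbour. Cells whose center
#' falls outside a source layer's footprint become nodata. Layers already on
#' the target grid are returned unchanged.
#'
#' @param layers a list of `inv_raster` (optionally named).
#' @param target the `inv_raster` defining the analysis grid.
#' @return list of aligned `inv_raster`s, same names as `layers`.
#' @export
align_stack <- function(layers, target) {
  if (inherits(layers, "inv_raster")) layers <- list(layers)
  lapply(layers, function(l) {
    if (!identical(l$crs, target$crs)) {
      stop("CRS mismatch (", l$crs, " vs ", target$crs,
           "); reprojection is not supported", call. = FALSE)
    }
    if (same_grid(l, target)) return(l)
    resample_onto(l, target)
  })
}

resample_onto <- function(l, target) {
  nr <- nrow(target$values); nc <- ncol(target$values)
  xt <- target$xmin + (seq_len(nc) - 0.5) * target$cellsize
  yt <- target$ymax - (seq_len(nr) - 0.5) * target$cellsize
  # fractional source index of each target cell center (1-based, center reg.)
  ci <- (rep(xt, each = nr) - l$xmin) / l$cellsize + 0.5
  ri <- (l$ymax - rep(yt, times = nc)) / l$cellsize + 0.5
  src <- l$values
  out <- rep(NA_real_, nr * nc)
  if (l$kind == "categorical") {
    rn <- round(ri); cn <- round(ci)
    ok <- rn >= 1 & rn <= nrow(src) & cn >= 1 & cn <= ncol(src)
    out[ok] <- src[cbind(rn[ok], cn[ok])]
  } else {
    r0 <- floor(ri); c0 <- floor(ci)
    fr <- ri - r0; fc <- ci - c0
    r0c <- pmin(pmax(r0, 1), nrow(src)); r1c <- pmin(pmax(r0 + 1, 1), nrow(src))
    c0c <- pmin(pmax(c0, 1), ncol(src)); c1c <- pmin(pmax(c0 + 1, 1), ncol(src))
    inside <- ri >= 0.5 & ri <= nrow(src) + 0.5 & ci >= 0.5 & ci <= ncol(src) + 0.5
    v00 <- src[cbind(r0c, c0c)]; v01 <- src[cbind(r0c, c1c)]
    v10 <- src[cbind(r1c, c0c)]; v11 <- src[cbind(r1c, c1c)]
    val <- (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
    # at the margin the clamped corners coincide; NA propagates from any corner
    out[inside] <- val[inside]
  }
  inv_raster(matrix(out, nr, nc), xmin = target$xmin, ymax = target$ymax,
             cellsize = target$cellsize, crs = target$crs,
             nodata = target$nodata, kind = l$kind, codes = l$codes)
}

#' Area of a binary mask
#'
#' All printed areas in the pipeline are cell tallies: the count of 1-cells
#' times a nominal cell area (default 1 km² for a 1-km grid). Geodesic
#' correction is deliberately out of scope.
#'
#' @param mask binary `inv_raster` (0/1, NA allowed).
#' @param cell_area nominal area of one cell in km².
#' @return area in km².
#' @export
area_of <- function(mask, cell_area = 1) {
  v <- mask$values[is.finite(mask$values)]
  if (length(v) && !all(v %in% c(0, 1))) {
    stop("`mask` must be binary (0/1)", call. = FALSE)
  }
  sum(v == 1) * cell_area
}

#' Convert a raster to a long tibble
#'
#' @param x an `inv_raster`.
#' @param ... unused.
#' @return tibble with `x`, `y`, `value` for every cell (nodata as `NA`).
#' @export
as_tibble.inv_raster <- function(x, ...) {
  cell_centers(x)[, c("x", "y", "value")]
}

map_raster <- function(r, f, kind = r$kind, codes = r$codes) {
  out <- r
  out$values <- matrix(f(r$values), nrow(r$values), ncol(r$values))
  out$kind <- kind
  out$codes <- codes
  out
}

const_like <- function(r, value = 0, kind = "continuous") {
  m <- matrix(value, nrow(r$values), ncol(r$values))
  inv_raster(m, xmin = r$xmin, ymax = r$ymax, cellsize = r$cellsize,
             crs = r$crs, nodata = r$nodata, kind = kind,
             codes = if (kind == "categorical") unique(as.integer(value)))
}
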