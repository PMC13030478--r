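#' Vector layers (points, lines, polygons)
#'
#' A minimal vector container: a list of features (each a `Point`,
#' `LineString` or `Polygon` geometry in the grid CRS) plus a tibble of
#' per-feature attributes. Polygons are lists of rings (first ring the
#' shell, later rings holes), each an n x 2 coordinate matrix; membership
#' uses the even-odd rule.
#'
#' @param features list of features, each `list(type =, coords =)`; for
#'   `Point` coords is `c(x, y)`, for `LineString` an n x 2 matrix, for
#'   `Polygon` a list of n x 2 ring matrices.
#' @param attributes tibble (or data.frame) with one row per feature.
#' @param crs CRS identifier, must match the target grid before rasterizing.
#' @return An object of class `inv_vector`.
#' @export
inv_vector <- function(features, attributes = NULL, crs = "EPSG:4326") {
  stopifnot(is.list(features))
  for (f in features) {
    stopifnot(is.list(f), f$type %in% c("Point", "LineString", "Polygon"))
    if (f$type == "Polygon") {
      for (ring in f$coords) {
        if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 3) {
          stop("polygon rings need >= 3 coordinate pairs", call. = FALSE)
        }
      }
    }
  }
  if (is.null(attributes)) {
    attributes <- tibble::tibble(.rows = length(features))
  } else {
    attributes <- tibble::as_tibble(attributes)
    stopifnot(nrow(attributes) == length(features))
  }
  structure(list(features = features, attributes = attributes, crs = crs),
            class = "inv_vector")
}

#' @export
print.inv_vector <- function(x, ...) {
  types <- vapply(x$features, `[[`, "", "type")
  cat(sprintf("<inv_vector> %d features (%s) in %s\n", length(types),
              paste(names(table(types)), table(types), collapse = ", "),
              x$crs))
  invisible(x)
}

#' @export
length.inv_vector <- function(x) length(x$features)

#' Shorthand vector-layer constructors
#'
#' `vec_polygon()` builds a polygon layer from ring matrices (one feature
#' per argument; pass a list of rings for holes); `vec_lines()` a polyline
#' layer from a list of coordinate matrices.
#'
#' @param ... ring matrices (n x 2), or lists of rings.
#' @param coords_list list of n x 2 polyline coordinate matrices.
#' @param attributes optional per-feature tibble.
#' @param crs CRS identifier.
#' @return an `inv_vector`.
#' @export
vec_polygon <- function(..., attributes = NULL, crs = "EPSG:4326") {
  rings <- list(...)
  feats <- lapply(rings, function(r) {
    list(type = "Polygon", coords = if (is.matrix(r)) list(r) else r)
  })
  inv_vector(feats, attributes, crs)
}

#' @rdname vec_polygon
#' @export
vec_lines <- function(coords_list, attributes = NULL, crs = "EPSG:4326") {
  inv_vector(lapply(coords_list, function(m) list(type = "LineString", coords = m)),
             attributes, crs)
}

#' Even-odd point-in-polygon test
#'
#' @param px,py point coordinates.
#' @param rings list of n x 2 ring matrices (shell first, holes after).
#' @return logical vector: inside under the even-odd rule. Points exactly on
#'   an edge are resolved by the half-open convention of the crossing test.
#' @export
point_in_polygon <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
    j <- c(n, seq_len(n - 1))
    for (k in seq_len(n)) {
      xi <- x[k]; yi <- y[k]; xj <- x[j[k]]; yj <- y[j[k]]
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
  }
  inside
}

ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

segments_self_intersect <- function(ring) {
  n <- nrow(ring) - 1L
  if (n < 3) return(FALSE)
  seg <- function(i) list(p = ring[i, ], q = ring[i + 1L, ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 2L)) {
    for (k in seq((i + 2L), n)) {
      if (i == 1L && k == n) next  # shared closing vertex
      a <- seg(i); b <- seg(k)
      d1 <- cross(b$p, b$q, a$p); d2 <- cross(b$p, b$q, a$q)
      d3 <- cross(a$p, a$q, b$p); d4 <- cross(a$p, a$q, b$q)
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Validate a vector layer
#'
#' Checks ring closure and simple (non-self-intersecting) polygon shells.
#'
#' @param layer an `inv_vector`.
#' @return `layer`, invisibly; errors on invalid geometry.
#' @export
validate_vector <- function(layer) {
  for (f in layer$features) {
    if (f$type == "Polygon") {
      for (ring in f$coords) {
        r <- ring
        if (!(r[1, 1] == r[nrow(r), 1] && r[1, 2] == r[nrow(r), 2])) {
          r <- rbind(r, r[1, ])
        }
        if (segments_self_intersect(r)) {
          stop("self-intersecting polygon ring", call. = FALSE)
        }
      }
    }
  }
  invisible(layer)
}

#' Read and write GeoJSON
#'
#' @param path file path.
#' @return `read_geojson()`: an `inv_vector`.
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path, call. = FALSE)
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(g$type, "FeatureCollection"))
  crs <- if (!is.null(g$crs)) g$crs else "EPSG:4326"
  feats <- lapply(g$features, function(f) {
    geom <- f$geometry
    co <- geom$coordinates
    switch(geom$type,
      Point = list(type = "Point", coords = c(co[[1]], co[[2]])),
      LineString = list(
        type = "LineString",
        coords = do.call(rbind, lapply(co, function(p) c(p[[1]], p[[2]])))
      ),
      Polygon = list(
        type = "Polygon",
        coords = lapply(co, function(ring) {
          do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
        })
      ),
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
  })
  props <- lapply(g$features, function(f) {
    p <- f$properties
    if (is.null(p) || !length(p)) tibble::tibble(.rows = 1) else tibble::as_tibble(p)
  })
  inv_vector(feats, dplyr::bind_rows(props), crs = crs)
}

#' @param layer an `inv_vector` to write.
#' @rdname read_geojson
#' @export
write_geojson <- function(layer, path) {
  feats <- purrr::map2(layer$features, seq_along(layer$features), function(f, i) {
    coords <- switch(f$type,
      Point = as.list(unname(f$coords)),
      LineString = apply(f$coords, 1, function(p) as.list(unname(p)),
                         simplify = FALSE),
      Polygon = lapply(f$coords, function(ring) {
        apply(ring, 1, function(p) as.list(unname(p)), simplify = FALSE)
      })
    )
    props <- if (ncol(layer$attributes)) {
      as.list(layer$attributes[i, , drop = FALSE])
    } else NULL
    list(type = "Feature",
         geometry = list(type = f$type, coordinates = coords),
         properties = props)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", crs = layer$crs, features = feats),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Rasterize a vector layer
#'
#' Presence mode marks every cell intersected by any geometry with 1.
#' Density mode accumulates intersected line length (or, for polygons,
#' covered area estimated on a 4 x 4 subcell lattice) per cell, divided by
#' the cell area, giving map-units per square map-unit (km per km² on the
#' nominal 1-km grid).
#'
#' @param layer an `inv_vector` in the target CRS.
#' @param target `inv_raster` defining the grid.
#' @param mode `"presence"` or `"density"`.
#' @return an `inv_raster` on the target grid.
#' @export
rasterize <- function(layer, target, mode = c("presence", "density")) {
  mode <- match.arg(mode)
  if (!identical(layer$crs, target$crs)) {
    stop("vector layer CRS differs from target grid CRS", call. = FALSE)
  }
  nr <- nrow(target$values); nc <- ncol(target$values)
  acc <- matrix(0, nr, nc)
  if (!length(layer$features)) {
    warning("empty vector layer: rasterized to all zeros")
  }
  for (f in layer$features) {
    if (f$type == "Point") {
      rc <- cell_of(target, f$coords[1], f$coords[2])
      if (!is.na(rc$row)) {
        acc[rc$row, rc$col] <- acc[rc$row, rc$col] +
          if (mode == "presence") 1 else 1 / target$cellsize^2
      }
    } else if (f$type == "LineString") {
      len <- line_lengths_per_cell(f$coords, target)
      if (mode == "presence") acc[len > 0] <- acc[len > 0] + 1
      else acc <- acc + len / target$cellsize^2
    } else {  # Polygon
      if (mode == "presence") {
        cc <- cell_centers(target)
        inside <- point_in_polygon(cc$x, cc$y, f$coords)
        acc[cbind(cc$row[inside], cc$col[inside])] <-
          acc[cbind(cc$row[inside], cc$col[inside])] + 1
      } else {
        frac <- polygon_cover_fraction(f$coords, target)
        acc <- acc + frac  # area / cell area = cover fraction
      }
    }
  }
  if (mode == "presence") acc <- (acc > 0) + 0
  out <- const_like(target, 0)
  out$values <- acc
  out$kind <- "continuous"
  out
}

# total length of a polyline inside each grid cell, by parametric traversal
line_lengths_per_cell <- function(coords, target) {
  nr <- nrow(target$values); nc <- ncol(target$values)
  cs <- target$cellsize
  out <- matrix(0, nr, nc)
  for (s in seq_len(nrow(coords) - 1L)) {
    p0 <- coords[s, ]; p1 <- coords[s + 1L, ]
    dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
    seg_len <- sqrt(dx^2 + dy^2)
    if (seg_len == 0) next
    ts <- c(0, 1)
    if (dx != 0) {
      # gridlines at x = xmin + m*cs for integer m
      m <- seq(floor((min(p0[1], p1[1]) - target$xmin) / cs),
               ceiling((max(p0[1], p1[1]) - target$xmin) / cs))
      tv <- (target$xmin + m * cs - p0[1]) / dx
      ts <- c(ts, tv[tv > 0 & tv < 1])
    }
    if (dy != 0) {
      m <- seq(floor((target$ymax - max(p0[2], p1[2])) / cs),
               ceiling((target$ymax - min(p0[2], p1[2])) / cs))
      yv <- target$ymax - m * cs
      tv <- (yv - p0[2]) / dy
      ts <- c(ts, tv[tv > 0 & tv < 1])
    }
    ts <- sort(unique(ts))
    for (i in seq_len(length(ts) - 1L)) {
      tm <- (ts[i] + ts[i + 1L]) / 2
      xm <- p0[1] + tm * dx; ym <- p0[2] + tm * dy
      rc <- cell_of(target, xm, ym)
      if (!is.na(rc$row)) {
        out[rc$row, rc$col] <- out[rc$row, rc$col] +
          (ts[i + 1L] - ts[i]) * seg_len
      }
    }
  }
  out
}

# covered-area fraction per cell on a 4x4 subcell-center lattice
polygon_cover_fraction <- function(rings, target, sub = 4L) {
  nr <- nrow(target$values); nc <- ncol(target$values)
  cs <- target$cellsize
  xs <- target$xmin + (rep(seq_len(nc * sub), each = nr * sub) - 0.5) * cs / sub
  ys <- target$ymax - (rep(seq_len(nr * sub), times = nc * sub) - 0.5) * cs / sub
  inside <- point_in_polygon(xs, ys, rings)
  fine <- matrix(inside, nr * sub, nc * sub)
  rowg <- (seq_len(nr * sub) - 1L) %/% sub + 1L
  colg <- (seq_len(nc * sub) - 1L) %/% sub + 1L
  agg <- rowsum(fine + 0, rowg)
  agg <- t(rowsum(t(agg), colg))
  agg / sub^2
}
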