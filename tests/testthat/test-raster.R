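test_that("ASCII grid round-trip preserves values, nodata and transform", {
  m <- matrix(1, 3, 3)
  m[2, 3] <- NA
  r <- inv_raster(m, xmin = 10, ymax = 20, cellsize = 0.5)
  path <- file.path(tempdir(), "rt.asc")
  write_raster(r, path)
  r2 <- read_raster(path)
  expect_equal(r2$values, r$values)
  expect_equal(r2$xmin, r$xmin)
  expect_equal(r2$ymax, r$ymax)
  expect_equal(r2$cellsize, r$cellsize)
  expect_identical(r2$crs, r$crs)
  # nodata cell stays masked in downstream statistics
  expect_equal(area_of(binarize(r2, 0.5)), 8)
})

test_that("reading without a CRS is refused", {
  r <- inv_raster(matrix(1, 2, 2))
  path <- file.path(tempdir(), "nocrs.asc")
  write_raster(r, path)
  file.remove(paste0(tools::file_path_sans_ext(path), ".prj"))
  expect_error(read_raster(path), "CRS")
  expect_silent(read_raster(path, crs = "EPSG:4326"))
  expect_error(read_raster(file.path(tempdir(), "missing.asc")), "not found")
})

test_that("raster invariants: cell size positive, categorical codes closed", {
  expect_error(inv_raster(matrix(1, 2, 2), cellsize = 0), "positive")
  expect_error(inv_raster(matrix(1.5, 2, 2), kind = "categorical"),
               "non-integer")
  expect_error(inv_raster(matrix(3, 2, 2), kind = "categorical", codes = 1:2),
               "outside")
  expect_error(inv_raster(matrix(1, 2, 2), kind = "categorical", codes = 1,
                          nodata = 1), "collides")
})

test_that("half-open cell ownership: edge points go south/east", {
  r <- inv_raster(matrix(0, 4, 4), xmin = 0, ymax = 4, cellsize = 1)
  # x = 2 lies on the shared edge between columns 2 and 3 -> east cell (3)
  expect_equal(cell_of(r, 2, 3.5)$col, 3L)
  # y = 2 lies on the shared edge between rows 2 and 3 -> south cell (3)
  expect_equal(cell_of(r, 0.5, 2)$row, 3L)
  expect_true(is.na(cell_of(r, 4, 1)$col))  # east boundary is outside
  expect_equal(cell_of(r, 0, 4)$row, 1L)    # north-west corner inside
})

test_that("align_stack: identity, categorical closure, constancy", {
  target <- inv_raster(matrix(0, 10, 10), xmin = 0, ymax = 10)
  same <- inv_raster(matrix(rnorm(100), 10, 10), xmin = 0, ymax = 10)
  expect_identical(align_stack(list(same), target)[[1]], same)

  fine_codes <- matrix(sample(c(2L, 5L, 9L), 400, TRUE), 20, 20)
  fine <- inv_raster(fine_codes, xmin = 0, ymax = 10, cellsize = 0.5,
                     kind = "categorical")
  al <- align_stack(list(fine), target)[[1]]
  expect_true(all(al$values %in% c(2, 5, 9)))

  const <- inv_raster(matrix(3.7, 30, 30), xmin = 0, ymax = 10,
                      cellsize = 1 / 3)
  alc <- align_stack(list(const), target)[[1]]
  expect_true(all(abs(alc$values - 3.7) < 1e-12))

  wrong_crs <- inv_raster(matrix(1, 10, 10), crs = "EPSG:3857", ymax = 10)
  expect_error(align_stack(list(wrong_crs), target), "CRS mismatch")
})

test_that("area_of counts cells and is additive over disjoint masks", {
  m <- matrix(0, 20, 20)
  m[1:10, 1:10] <- 1
  a <- inv_raster(m, ymax = 20)
  expect_equal(area_of(a), 100)
  expect_equal(area_of(binarize(a, 2)), 0)  # empty mask
  m2 <- matrix(0, 20, 20); m2[11:20, 11:20] <- 1
  b <- inv_raster(m2, ymax = 20)
  both <- inv_raster(m + m2, ymax = 20)
  expect_equal(area_of(both), area_of(a) + area_of(b))
  expect_error(area_of(inv_raster(matrix(2, 2, 2))), "binary")
  # printed-area arithmetic: core minus protected part gives the gap
  expect_equal(20.10e4 - 2.25e4, 17.85e4)
})

test_that("rasterize covers presence, line density and the empty case", {
  target <- inv_raster(matrix(0, 6, 6), xmin = 0, ymax = 6)
  # polygon covering exactly cells (rows 1-2) x (cols 1-2)
  sq <- vec_polygon(cbind(c(0, 2, 2, 0, 0), c(6, 6, 4, 4, 6)))
  pres <- rasterize(sq, target, mode = "presence")
  expect_equal(sum(pres$values), 4)
  expect_equal(pres$values[1:2, 1:2], matrix(1, 2, 2))

  # straight 2-km line through one column: total length / cell area
  ln <- vec_lines(list(cbind(c(0.5, 0.5), c(5.5, 3.5))))
  dens <- rasterize(ln, target, mode = "density")
  expect_equal(sum(dens$values), 2)          # 2 km total per km^2 cells
  expect_equal(dens$values[1, 1], 0.5)       # 0.5 km inside the first cell

  expect_warning(z <- rasterize(inv_vector(list()), target), "empty")
  expect_true(all(z$values == 0))
})

test_that("point-in-polygon handles holes via the even-odd rule", {
  shell <- cbind(c(0, 4, 4, 0, 0), c(0, 0, 4, 4, 0))
  hole <- cbind(c(1, 3, 3, 1, 1), c(1, 1, 3, 3, 1))
  expect_true(point_in_polygon(0.5, 0.5, list(shell, hole)))
  expect_false(point_in_polygon(2, 2, list(shell, hole)))
  expect_false(point_in_polygon(5, 5, list(shell, hole)))
  bow <- cbind(c(0, 2, 0, 2, 0), c(0, 2, 2, 0, 0))
  expect_error(validate_vector(vec_polygon(bow)), "self-intersecting")
})

test_that("GeoJSON round-trips geometry and attributes", {
  layer <- inv_vector(
    list(list(type = "Point", coords = c(1.5, 2.5)),
         list(type = "LineString", coords = cbind(c(0, 1, 2), c(0, 1, 0))),
         list(type = "Polygon",
              coords = list(cbind(c(0, 2, 2, 0, 0), c(0, 0, 2, 2, 0))))),
    attributes = tibble::tibble(name = c("a", "b", "c")))
  path <- file.path(tempdir(), "layer.geojson")
  write_geojson(layer, path)
  back <- read_geojson(path)
  expect_equal(length(back), 3L)
  expect_equal(back$features[[1]]$coords, c(1.5, 2.5))
  expect_equal(back$features[[2]]$coords, layer$features[[2]]$coords)
  expect_equal(back$features[[3]]$coords[[1]], layer$features[[3]]$coords[[1]])
  expect_equal(back$attributes$name, c("a", "b", "c"))
})
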