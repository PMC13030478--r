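bin <- function(m) inv_raster(m, ymax = nrow(m))

test_that("core habitat is the mask intersection with exclusive remainders", {
  s <- bin(matrix(c(1, 1, 0, 0), 2, 2))
  v <- bin(matrix(c(1, 0, 1, 0), 2, 2))
  pm <- core_habitat(s, v)
  expect_equal(pm$map$values[1, 1], 3)  # both
  expect_equal(pm$map$values[2, 1], 1)  # suitability only
  expect_equal(pm$map$values[1, 2], 2)  # vulnerability only
  expect_equal(pm$map$values[2, 2], 0)
  same <- core_habitat(s, s)
  expect_equal(sum(same$map$values == 3), 2)
  expect_equal(sum(same$map$values %in% c(1, 2)), 0)
  disj <- core_habitat(bin(matrix(c(1, 0, 0, 0), 2, 2)),
                       bin(matrix(c(0, 1, 0, 0), 2, 2)))
  expect_equal(sum(disj$map$values == 3), 0)
  # intersection bound
  expect_lte(sum(pm$map$values == 3), min(area_of(s), area_of(v)))
})

test_that("gap analysis reproduces the printed national arithmetic", {
  # 2010 core cells at 100 km^2 nominal cell area = 20.10e4 km^2 of core;
  # 225 protected -> 2.25e4 protected, 17.85e4 gap, 11.18% / 88.82%
  core <- matrix(0, 50, 50)
  core[1:45, 1:45] <- 1
  core[50, 50] <- 0
  core_cells <- which(core == 1)[1:2010]
  core[] <- 0; core[core_cells] <- 1
  pa <- matrix(0, 50, 50); pa[core_cells[1:225]] <- 1
  rep <- gap_analysis(bin(core), bin(pa), cell_area = 100)
  g <- glance(rep)
  expect_equal(g$core_km2, 20.10e4)
  expect_equal(g$protected_km2, 2.25e4)
  expect_equal(g$gap_km2, 17.85e4)
  expect_equal(g$protected_pct, 11.18, tolerance = 0.005)
  expect_equal(g$gap_pct, 88.82, tolerance = 0.005)
  expect_equal(g$protected_pct + g$gap_pct, 100, tolerance = 1e-9)
})

test_that("gap analysis rasterizes PA polygons and handles edge cases", {
  core <- bin(matrix(1, 10, 10))
  pa_all <- vec_polygon(cbind(c(-1, 11, 11, -1, -1), c(-1, -1, 11, 11, -1)))
  rep <- gap_analysis(core, pa_all)
  expect_equal(glance(rep)$gap_km2, 0)
  expect_warning(rep0 <- gap_analysis(core, inv_vector(list())), "empty")
  expect_equal(glance(rep0)$gap_pct, 100)
})

test_that("composition tallies proportions that sum to one", {
  lulc <- inv_raster(matrix(c(1L, 1L, 2L, 3L), 2, 2), ymax = 2,
                     kind = "categorical")
  mask <- bin(matrix(1, 2, 2))
  comp <- composition(mask, lulc)
  expect_equal(sum(comp$proportion), 1, tolerance = 1e-9)
  expect_equal(comp$proportion[comp$class == 1], 0.5)
  single <- composition(bin(matrix(c(1, 1, 0, 0), 2, 2)), lulc)
  expect_equal(single$proportion, 1)        # mask entirely within class 1
  expect_error(composition(bin(matrix(0, 2, 2)), lulc), "empty")
  # brute-force tally
  set.seed(71)
  big <- inv_raster(matrix(sample(1:7, 900, TRUE), 30, 30), ymax = 30,
                    kind = "categorical")
  m <- bin(matrix(rbinom(900, 1, 0.3), 30, 30))
  comp2 <- composition(m, big)
  for (k in comp2$class) {
    expect_equal(comp2$n_cells[comp2$class == k],
                 sum(big$values == k & m$values == 1))
  }
})

test_that("composition of the core ignores input mask order", {
  set.seed(73)
  s <- bin(matrix(rbinom(100, 1, 0.5), 10, 10))
  v <- bin(matrix(rbinom(100, 1, 0.5), 10, 10))
  lulc <- inv_raster(matrix(sample(1:3, 100, TRUE), 10, 10), ymax = 10,
                     kind = "categorical")
  m1 <- core_habitat(s, v)
  m2 <- core_habitat(v, s)
  c1 <- composition(invrisk:::category_mask(m1, 3), lulc)
  c2 <- composition(invrisk:::category_mask(m2, 3), lulc)
  expect_equal(c1, c2)
})

test_that("pathway dominance: trivial cases and weight-driven ranking", {
  lulc <- inv_raster(matrix(1L, 12, 12), ymax = 12, kind = "categorical")
  sens <- tibble::tibble(lulc = 1L, highway = 1, railway = 1, river = 1)
  specs <- threat_table()
  ones <- inv_raster(matrix(1, 12, 12), ymax = 12)
  zeros <- inv_raster(matrix(0, 12, 12), ymax = 12)
  only_h <- pathway_dominance(list(highway = ones, railway = zeros,
                                   river = zeros), specs, sens, lulc)
  expect_equal(only_h$summary$dominance_fraction[
    only_h$summary$pathway == "highway"], 1)
  # equal fields everywhere: weights decide the ranking, ties go to the
  # first-listed pathway
  eq <- pathway_dominance(list(highway = ones, railway = ones, river = ones),
                          specs, sens, lulc)
  risks <- eq$summary$mean_corridor_risk
  names(risks) <- eq$summary$pathway
  expect_true(risks["highway"] > risks["railway"] &&
                risks["railway"] > risks["river"])
  expect_equal(unname(eq$summary$dominance_fraction[
    eq$summary$pathway == "highway"]), 1)
  two_eq <- pathway_dominance(list(railway = ones, river = ones),
                              specs, sens, lulc)
  expect_equal(unname(two_eq$summary$dominance_fraction[
    two_eq$summary$pathway == "railway"]), 1)   # tie-break by listing order
  expect_warning(
    none <- pathway_dominance(list(highway = zeros), specs, sens, lulc),
    "dominance undefined")
  expect_equal(nrow(none$summary), 0)
})

test_that("pathway hotspots are contained in the corridor footprint", {
  set.seed(79)
  lulc <- inv_raster(matrix(1L, 20, 20), ymax = 20, kind = "categorical")
  sens <- tibble::tibble(lulc = 1L, highway = 1, railway = 0.8, river = 0.6)
  f <- lapply(1:3, function(i) {
    src <- matrix(0, 20, 20); src[sample(400, 4)] <- 1
    threat_field(inv_raster(src, ymax = 20), 5, "linear")
  })
  names(f) <- c("highway", "railway", "river")
  pr <- pathway_dominance(f, threat_table(), sens, lulc, seed = 3)
  for (i in 1:3) {
    nm <- pr$summary$pathway[i]
    corridor <- f[[nm]]$values > 0
    expect_lte(pr$summary$hotspot_area_km2[i], sum(corridor))
    expect_lte(pr$summary$largest_hotspot_km2[i],
               pr$summary$hotspot_area_km2[i])
  }
  expect_lte(sum(pr$summary$dominance_fraction), 1 + 1e-12)
})
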