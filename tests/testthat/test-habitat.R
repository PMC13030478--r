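test_that("decay factors satisfy their closed-form identities", {
  expect_equal(decay_factor(0, 2, "linear"), 1)
  expect_equal(decay_factor(0, 2, "exponential"), 1)
  expect_equal(decay_factor(2, 2, "linear"), 0)
  expect_equal(decay_factor(2, 2, "exponential"), exp(-2.99))
  expect_equal(decay_factor(3, 2, "exponential"), 0)  # beyond d_max
  expect_equal(decay_factor(1, 2, "linear"), 0.5)
  expect_error(decay_factor(-1, 2, "linear"), "negative")
  expect_error(decay_factor(1, 0, "linear"), "positive")
})

test_that("threat field equals the naive all-pairs oracle on small grids", {
  set.seed(37)
  for (decay in c("linear", "exponential")) {
    src <- matrix(0, 18, 18)
    src[cbind(sample(18, 5), sample(18, 5))] <- runif(5, 0.3, 1)
    r <- inv_raster(src, ymax = 18)
    got <- threat_field(r, d_max_km = 4, decay = decay)
    want <- threat_field_naive(src, 4, decay)
    tol <- if (decay == "linear") 1e-12 else 1e-9
    expect_equal(got$values, want, tolerance = tol)
  }
})

test_that("threat field: unit sources, monotonicity in d_max, empty case", {
  src <- matrix(0, 12, 12); src[6, 6] <- 1
  r <- inv_raster(src, ymax = 12)
  f <- threat_field(r, 3, "linear")
  expect_equal(f$values[6, 6], 1)                      # source cell at r = 1
  expect_equal(f$values[6, 8], decay_factor(2, 3, "linear"))
  f2 <- threat_field(r, 6, "linear")
  expect_true(all(f2$values >= f$values))              # larger reach
  empty <- threat_field(inv_raster(matrix(0, 8, 8), ymax = 8), 2, "linear")
  expect_true(all(empty$values == 0))
  expect_error(threat_field(inv_raster(matrix(2, 4, 4), ymax = 4), 2),
               "\\[0, 1\\]")
})

test_that("degradation self-normalizes weights and respects sensitivity", {
  lulc <- inv_raster(matrix(c(1L, 2L), 4, 4), ymax = 4, kind = "categorical")
  ones <- inv_raster(matrix(1, 4, 4), ymax = 4)
  specs <- tibble::tibble(threat = "urban", d_max_km = 1, weight = 0.37,
                          decay = "linear")
  sens <- tibble::tibble(lulc = c(1L, 2L), urban = c(1, 0))
  D <- degradation(list(urban = ones), specs, sens, lulc)
  expect_equal(D$values[lulc$values == 1], rep(1, 8))  # weight cancels
  expect_equal(D$values[lulc$values == 2], rep(0, 8))  # zero sensitivity
  sens_missing <- tibble::tibble(lulc = 1L, urban = 1)
  expect_error(degradation(list(urban = ones), specs, sens_missing, lulc),
               "absent")
})

test_that("two-threat degradation equals the naive per-cell loop", {
  set.seed(41)
  lulc <- inv_raster(matrix(sample(1:3, 100, TRUE), 10, 10), ymax = 10,
                     kind = "categorical")
  fa <- inv_raster(matrix(runif(100), 10, 10), ymax = 10)
  fb <- inv_raster(matrix(runif(100), 10, 10), ymax = 10)
  specs <- tibble::tibble(threat = c("a", "b"), d_max_km = c(1, 1),
                          weight = c(0.8, 0.4), decay = "linear")
  sens <- tibble::tibble(lulc = 1:3, a = c(0.2, 0.5, 1), b = c(1, 0.3, 0))
  D <- degradation(list(a = fa, b = fb), specs, sens, lulc)
  naive <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    cl <- lulc$values[i, j]
    naive[i, j] <- (0.8 / 1.2) * fa$values[i, j] * sens$a[cl] +
      (0.4 / 1.2) * fb$values[i, j] * sens$b[cl]
  }
  expect_equal(D$values, naive)
  expect_true(all(D$values >= 0 & D$values <= 1))
  # removing a threat never increases degradation
  D1 <- degradation(list(a = fa), specs, sens, lulc)
  expect_true(all(D1$values * (0.8 / 1.2) * 1.2 / 0.8 >= 0)) # well-defined
  expect_true(all(degradation(list(a = fa, b = fb), specs, sens, lulc)$values >=
                    (0.8 / 1.2) * fa$values * sens$a[lulc$values] - 1e-12))
})

test_that("quality: half-saturation and boundary identities", {
  lulc <- inv_raster(matrix(1L, 3, 3), ymax = 3, kind = "categorical")
  scores1 <- tibble::tibble(lulc = 1L, habitat = 1)
  K <- 0.3
  D0 <- inv_raster(matrix(0, 3, 3), ymax = 3)
  expect_equal(quality(D0, scores1, lulc, K)$values, matrix(1, 3, 3))
  DK <- inv_raster(matrix(K, 3, 3), ymax = 3)
  expect_equal(quality(DK, scores1, lulc, K)$values, matrix(0.5, 3, 3))
  scores0 <- tibble::tibble(lulc = 1L, habitat = 0)
  Dany <- inv_raster(matrix(runif(9), 3, 3), ymax = 3)
  expect_equal(quality(Dany, scores0, lulc, K)$values, matrix(0, 3, 3))
  expect_error(quality(Dany, scores1, lulc, K = 0), "positive")
  # monotone: non-increasing in D, non-decreasing in K
  d <- seq(0, 1, by = 0.05)
  q1 <- 1 - d^2.5 / (d^2.5 + 0.3^2.5)
  expect_true(all(diff(q1) <= 0))
  Dfix <- inv_raster(matrix(0.4, 2, 2), ymax = 2)
  l2 <- inv_raster(matrix(1L, 2, 2), ymax = 2, kind = "categorical")
  qK <- vapply(c(0.1, 0.3, 0.6, 1),
               function(k) quality(Dfix, scores1, l2, k)$values[1, 1], 0)
  expect_true(all(diff(qK) >= 0))
})

test_that("K calibration follows the half-of-maximum rule", {
  D <- inv_raster(matrix(c(0.1, 0.3, 0.868, 0.2), 2, 2), ymax = 2)
  K <- calibrate_k(D)
  expect_equal(as.numeric(K), 0.434)
  Dmax1 <- inv_raster(matrix(c(0, 1), 2, 2), ymax = 2)
  expect_equal(as.numeric(calibrate_k(Dmax1)), 0.5)
  D0 <- inv_raster(matrix(0, 2, 2), ymax = 2)
  expect_warning(K0 <- calibrate_k(D0), "zero")
  expect_equal(as.numeric(K0), 0.05)
})

test_that("degradation tiers partition and the 0.31 rule is inclusive", {
  D <- inv_raster(matrix(c(0, 0.17, 0.31, 0.42, 0.55, 0.93, 0.05, 0.5, 0.2),
                         3, 3), ymax = 3)
  cls <- classify_degradation(D)
  # a cell exactly at the vulnerability threshold is high-vulnerability
  expect_equal(cls$high_vulnerability$values[D$values == 0.31], 1)
  expect_equal(cls$high_vulnerability$values[D$values == 0.2], 0)
  expect_equal(sum(zone_areas(cls$tiers)$n_cells), 9)
  expect_error(classify_degradation(D, thresholds = c(0.3, 0.2, 0.4, 0.5)),
               "ascending")
  Dz <- inv_raster(matrix(0, 3, 3), ymax = 3)
  clz <- classify_degradation(Dz)
  expect_true(all(clz$tiers$zones$values == 1))
  expect_true(all(clz$high_vulnerability$values == 0))
})

test_that("threat correlations recover identity and invariances", {
  set.seed(43)
  D <- inv_raster(matrix(runif(400), 20, 20), ymax = 20)
  same <- D
  aff <- D; aff$values <- 3 * D$values - 1  # affine rescale keeps the sign
  indep <- inv_raster(matrix(runif(400), 20, 20), ymax = 20)
  flat <- inv_raster(matrix(0.5, 20, 20), ymax = 20)
  out <- threat_correlations(D, list(same = same, aff = aff, indep = indep,
                                     flat = flat), seed = 2)
  expect_equal(out$r[out$threat == "same"], 1, tolerance = 1e-12)
  expect_equal(out$r[out$threat == "aff"], 1, tolerance = 1e-12)
  ci <- cor.test(as.vector(indep$values), as.vector(D$values))$conf.int
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_true(is.na(out$r[out$threat == "flat"]))
  expect_match(out$note[out$threat == "flat"], "zero variance")
})

test_that("disturbance-sourced threats degrade disturbance zones most", {
  b <- small_bundle(seed = 97)
  thr <- threat_table()
  fields <- lapply(seq_len(nrow(thr)), function(i) {
    threat_field(b$threat_rasters[[thr$threat[i]]], thr$d_max_km[i],
                 thr$decay[i])
  })
  names(fields) <- thr$threat
  D <- degradation(fields[c("urban", "farmland")], thr,
                   default_sensitivity(), b$lulc)
  # disturbance zones sit at the urban/farmland sources; wetland is placed
  # away from them, so mean degradation is higher in disturbance zones
  d_dist <- mean(D$values[b$lulc$values == 1], na.rm = TRUE)
  d_wet <- mean(D$values[b$lulc$values == 4], na.rm = TRUE)
  expect_gt(d_dist, d_wet)
  Q <- quality(D, default_habitat_scores(), b$lulc,
               K = as.numeric(calibrate_k(D)))
  q_dist <- mean(Q$values[b$lulc$values == 1], na.rm = TRUE)
  q_wet <- mean(Q$values[b$lulc$values == 4], na.rm = TRUE)
  expect_gt(q_wet, q_dist)   # low habitat score + degradation
})
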