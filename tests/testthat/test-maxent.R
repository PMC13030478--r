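# a tiny 1-feature world used for closed-form checks: a binary variable
binary_world <- function(p_presence = 0.8, p_background = 0.5,
                         m = 200, n = 1000) {
  list(presence = data.frame(v = rep(c(1, 0), round(c(p_presence, 1 - p_presence) * m))),
       background = data.frame(v = rep(c(1, 0), round(c(p_background, 1 - p_background) * n))))
}

test_that("no signal gives a zero weight at the penalized optimum", {
  w <- binary_world(0.5, 0.5)
  fit <- fit_maxent(w$presence, w$background, classes = "linear")
  expect_equal(unname(fit$lambda), 0)
  expect_true(fit$converged)
})

test_that("one-feature fit matches a brute-force likelihood scan", {
  w <- binary_world(0.8, 0.5)
  fit <- fit_maxent(w$presence, w$background, classes = "linear", beta = 0)
  # oracle: direct 1-D scan of the unpenalized presence log-likelihood on
  # the standardized feature
  f_bg <- (w$background$v - mean(w$background$v)) / stats::sd(w$background$v)
  f_p <- (w$presence$v - mean(w$background$v)) / stats::sd(w$background$v)
  nll <- function(l) -mean(f_p * l) + log(mean(exp(f_bg * l)))
  oracle <- stats::optimize(nll, c(-10, 10), tol = 1e-10)$minimum
  expect_equal(unname(fit$lambda), oracle, tolerance = 1e-4)
  # independent cross-check with a penalized-regression solver where
  # available (maxent's background expectation equals an intercept-adjusted
  # Poisson/logistic fit in one dimension; here we recheck the scan itself)
  grid <- seq(-5, 5, by = 1e-4)
  expect_equal(oracle, grid[which.min(vapply(grid, nll, 0))], tolerance = 1e-3)
})

test_that("KKT box condition holds at every converged fit", {
  set.seed(42)
  pres <- data.frame(a = rnorm(60, 1), b = rnorm(60, -0.5), c = rnorm(60))
  bg <- data.frame(a = rnorm(2000), b = rnorm(2000), c = rnorm(2000))
  fit <- fit_maxent(pres, bg)
  expect_true(fit$converged)
  # recompute |E_model f - E_presence f| directly from the fitted object
  defs <- fit$defs
  Fb <- invrisk:::feature_matrix(bg, defs)
  Fp <- invrisk:::feature_matrix(pres, defs)
  Fb <- sweep(sweep(Fb, 2, fit$center), 2, fit$scale, "/")
  Fp <- sweep(sweep(Fp, 2, fit$center), 2, fit$scale, "/")
  s <- drop(Fb %*% fit$lambda)
  q <- exp(s - max(s)); q <- q / sum(q)
  gap <- abs(drop(crossprod(Fb, q)) - colMeans(Fp))
  expect_true(all(gap <= fit$beta + 1e-4))
})

test_that("zero-variance features are dropped with a warning", {
  pres <- data.frame(a = rnorm(30), k = 1)
  bg <- data.frame(a = rnorm(500), k = 1)
  expect_warning(fit <- fit_maxent(pres, bg), "no background variance")
  expect_false(any(grepl("^k", names(fit$lambda))))
  expect_error(fit_maxent(pres[1:3, ], bg), "at least 5")
})

test_that("AUC equals exhaustive pair counting with half ties", {
  expect_equal(evaluate_auc(c(0.9, 0.8), c(0.7, 0.6, 0.5)), 1.0)
  expect_equal(evaluate_auc(c(0.8, 0.4), c(0.6, 0.2)), 0.75)
  expect_equal(evaluate_auc(rep(0.3, 4), rep(0.3, 6)), 0.5)
  set.seed(3)
  p <- runif(23); b <- runif(57)
  pairs <- outer(p, b, function(x, y) (x > y) + 0.5 * (x == y))
  expect_equal(evaluate_auc(p, b), mean(pairs))
  # invariance under strictly monotone transforms
  expect_equal(evaluate_auc(exp(3 * p), exp(3 * b)), evaluate_auc(p, b))
  expect_error(evaluate_auc(numeric(), b), "empty")
})

test_that("max-SSS threshold equals the exhaustive scan", {
  thr <- threshold_max_sss(c(0.9, 0.8, 0.2), c(0.6, 0.3, 0.1))
  expect_equal(thr$threshold, 0.8)
  expect_equal(thr$sensitivity + thr$specificity, 2 / 3 + 1)
  # perfectly separated scores: smallest presence score above background
  sep <- threshold_max_sss(c(0.7, 0.9), c(0.1, 0.2))
  expect_equal(sep$threshold, 0.7)
  # random case vs brute force over all candidate thresholds
  set.seed(11)
  p <- round(runif(15), 2); b <- round(runif(40), 2)
  cand <- sort(unique(p))
  ss <- vapply(cand, function(t) mean(p >= t) + mean(b < t), 0)
  expect_equal(threshold_max_sss(p, b)$threshold, cand[which.max(ss)])
})

test_that("binarized cells are exactly those with HSI >= threshold", {
  hsi <- inv_raster(matrix(seq(0, 1, length.out = 25), 5, 5), ymax = 5)
  bm <- binarize(hsi, 0.5)
  expect_identical(bm$values == 1, hsi$values >= 0.5)
  expect_equal(attr(bm, "threshold"), 0.5)
})

test_that("replicate_run reduces to a single fit and is seed-stable", {
  b <- small_bundle(seed = 83)
  bg <- sample_background(build_bias_surface(b$occurrences, b$env[[1]]),
                          1500, seed = 85)
  rec <- b$occurrences[b$occurrences$species == "sp02", ]
  one <- replicate_run(rec, b$env, bg, n_replicates = 1, seed = 87,
                       species = "sp02")
  expect_equal(nrow(one$replicates), 1)
  again <- replicate_run(rec, b$env, bg, n_replicates = 1, seed = 87,
                         species = "sp02")
  expect_identical(one$hsi$values, again$hsi$values)
  expect_identical(one$threshold, again$threshold)

  multi <- replicate_run(rec, b$env, bg, n_replicates = 3, seed = 89,
                         species = "sp02")
  # mean-HSI raster is bounded cell-wise by the replicate min/max
  expect_true(all(multi$hsi$values >= multi$hsi_range$min - 1e-12, na.rm = TRUE))
  expect_true(all(multi$hsi$values <= multi$hsi_range$max + 1e-12, na.rm = TRUE))
  expect_true(all(multi$hsi$values >= 0 & multi$hsi$values <= 1, na.rm = TRUE))
})

test_that("contributions: absent variables get 0%, totals are 100%", {
  set.seed(13)
  # species driven by `a` only; `b` independent noise
  bg <- data.frame(a = rnorm(1500), b = rnorm(1500))
  pres <- data.frame(a = rnorm(80, sd = 0.25), b = rnorm(80))
  fit <- fit_maxent(pres, bg)
  sdm <- structure(list(model = fit, presence_env = pres, background_env = bg,
                        species = "toy"), class = "maxent_sdm")
  vc <- variable_contributions(sdm, seed = 15)
  expect_equal(sum(vc$contributions$contribution_pct), 100, tolerance = 1e-6)
  expect_gt(vc$contributions$contribution_pct[vc$contributions$variable == "a"], 60)
  # jackknife: the only-a model gains more than the only-b model
  jk <- vc$jackknife
  expect_gt(jk$gain_only[jk$variable == "a"], jk$gain_only[jk$variable == "b"])
})
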