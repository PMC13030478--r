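#' Presence-background maximum-entropy species distribution model
#'
#' Fits the Gibbs density p(x) = exp(lambda . f(x)) / Z over background
#' cells by minimizing the regularized negative presence log-likelihood
#'
#'   L(lambda) = -mean_presence[lambda . f] + log mean_bg[exp(lambda . f)]
#'               + sum_j beta_j |lambda_j|
#'
#' by proximal-Newton iterations: an IRLS quadratic model of the
#' log-partition term, an inner L1 coordinate-descent solve, and a
#' backtracking line search.
#' Features are linear and quadratic terms of each environmental variable
#' (product terms available), z-scored over the background sample.
#' Convergence is declared when the largest KKT violation
#' |E_model f_j - E_presence f_j| - beta_j (for zero weights) falls below
#' `tol`; otherwise the fit is returned flagged, never silently.
#'
#' The per-feature L1 penalties default to a published sample-size-keyed
#' schedule for the linear+quadratic class: beta_j = `reg_multiplier` *
#' interp(m) * sd_presence(f_j) / sqrt(m), with interp linear over
#' m = (10, 30, 100) -> (1.0, 0.6, 0.5), m the presence count.
#'
#' @param presence data frame of environmental values at presence points.
#' @param background data frame of environmental values at background points
#'   (same columns).
#' @param classes feature classes to build, subset of
#'   `c("linear", "quadratic", "product")`.
#' @param reg_multiplier multiplier on the default regularization schedule.
#' @param beta optional explicit per-feature penalty vector (recycled);
#'   overrides the schedule (0 = unregularized).
#' @param max_iter iteration cap (default 500).
#' @param tol KKT tolerance for convergence.
#' @param tau prevalence offset of the logistic output (default 0.5).
#' @return an object of class `inv_maxent`.
#' @export
fit_maxent <- function(presence, background,
                       classes = c("linear", "quadratic"),
                       reg_multiplier = 1.0, beta = NULL,
                       max_iter = 500, tol = 1e-5, tau = 0.5) {
  presence <- as.data.frame(presence)
  background <- as.data.frame(background)
  stopifnot(identical(sort(names(presence)), sort(names(background))))
  background <- background[names(presence)]
  m <- nrow(presence)
  if (m < 5) stop("need at least 5 presence records", call. = FALSE)
  defs <- feature_defs(names(presence), classes)
  Fp <- feature_matrix(presence, defs)
  Fb <- feature_matrix(background, defs)
  # standardize over background; drop features without variance there
  ctr <- colMeans(Fb)
  scl <- apply(Fb, 2, stats::sd)
  keep <- scl > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d feature(s) with no background variance",
                    sum(!keep)))
    defs <- defs[keep, , drop = FALSE]
    Fp <- Fp[, keep, drop = FALSE]; Fb <- Fb[, keep, drop = FALSE]
    ctr <- ctr[keep]; scl <- scl[keep]
  }
  if (!ncol(Fp)) stop("no usable features", call. = FALSE)
  Fp <- sweep(sweep(Fp, 2, ctr), 2, scl, "/")
  Fb <- sweep(sweep(Fb, 2, ctr), 2, scl, "/")
  if (is.null(beta)) {
    sched <- stats::approx(x = c(10, 30, 100), y = c(1.0, 0.6, 0.5),
                           xout = min(max(m, 10), 100), rule = 2)$y
    beta <- reg_multiplier * sched * apply(Fp, 2, stats::sd) / sqrt(m)
  } else {
    beta <- rep_len(beta, ncol(Fp))
  }
  pbar <- colMeans(Fp)
  lambda <- numeric(ncol(Fp))
  smooth_loss <- function(l) {
    s <- drop(Fb %*% l)
    mx <- max(s)
    -sum(pbar * l) + mx + log(mean(exp(s - mx)))
  }
  grad_at <- function(l) {
    s <- drop(Fb %*% l)
    q <- exp(s - max(s)); q <- q / sum(q)
    drop(crossprod(Fb, q)) - pbar
  }
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  kkt_violation <- function(g, l) {
    v <- ifelse(l > 0, abs(g + beta),
                ifelse(l < 0, abs(g - beta), pmax(abs(g) - beta, 0)))
    max(v)
  }
  # proximal Newton: IRLS quadratic model of the log-partition term with an
  # inner L1 coordinate-descent solve, plus backtracking line search
  p <- ncol(Fb)
  iter <- 0L; kkt <- Inf
  loss <- smooth_loss(lambda)
  while (iter < max_iter) {
    iter <- iter + 1L
    s <- drop(Fb %*% lambda)
    q <- exp(s - max(s)); q <- q / sum(q)
    g <- drop(crossprod(Fb, q)) - pbar
    kkt <- kkt_violation(g, lambda)
    if (kkt <= tol) break
    Fq <- drop(crossprod(Fb, q))
    H <- crossprod(Fb * sqrt(q)) - tcrossprod(Fq)
    diag(H) <- diag(H) + 1e-8
    # inner: argmin_d g'd + d'Hd/2 + sum beta |lambda + d|
    d <- numeric(p)
    for (sweep in seq_len(60)) {
      delta_max <- 0
      for (j in seq_len(p)) {
        gj <- g[j] + sum(H[j, ] * d)
        hj <- H[j, j]
        zj <- lambda[j] + d[j] - gj / hj
        newv <- soft(zj, beta[j] / hj) - lambda[j]
        delta_max <- max(delta_max, abs(newv - d[j]))
        d[j] <- newv
      }
      if (delta_max < 1e-10) break
    }
    if (max(abs(d)) == 0) break
    step <- 1
    pen0 <- sum(beta * abs(lambda))
    repeat {
      cand <- lambda + step * d
      lc <- smooth_loss(cand)
      dec <- sum(g * d) + sum(beta * abs(lambda + d)) - pen0
      if (lc + sum(beta * abs(cand)) <=
            loss + pen0 + 0.25 * step * dec + 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    lambda <- lambda + step * d
    loss <- smooth_loss(lambda)
  }
  g <- grad_at(lambda)
  kkt <- kkt_violation(g, lambda)
  loss <- smooth_loss(lambda)
  converged <- kkt <= tol
  if (!converged) {
    inv_msg("maxent fit stopped at iteration cap (KKT violation %.2e)", kkt)
  }
  s <- drop(Fb %*% lambda)
  mx <- max(s)
  lse <- mx + log(sum(exp(s - mx)))       # log sum over bg points
  q <- exp(s - lse)
  entropy <- -sum(q * log(pmax(q, 1e-300)))
  structure(list(
    defs = defs, lambda = stats::setNames(lambda, defs$feature),
    beta = stats::setNames(beta, defs$feature),
    center = ctr, scale = scl, lse = lse, entropy = entropy, tau = tau,
    n_presence = m, n_background = nrow(Fb),
    converged = converged, n_iter = iter, kkt = kkt,
    gain = -(loss),  # regularization excluded: training gain vs null model
    settings = list(classes = classes, reg_multiplier = reg_multiplier,
                    max_iter = max_iter, tol = tol, tau = tau)
  ), class = "inv_maxent")
}

feature_defs <- function(vars, classes) {
  defs <- list()
  if ("linear" %in% classes) {
    defs <- c(defs, list(tibble::tibble(variable = vars, class = "linear")))
  }
  if ("quadratic" %in% classes) {
    defs <- c(defs, list(tibble::tibble(variable = vars, class = "quadratic")))
  }
  if ("product" %in% classes && length(vars) > 1) {
    pairs <- utils::combn(vars, 2)
    defs <- c(defs, list(tibble::tibble(
      variable = paste(pairs[1, ], pairs[2, ], sep = ":"), class = "product")))
  }
  out <- dplyr::bind_rows(defs)
  out$feature <- paste(out$variable, out$class, sep = ".")
  out
}

feature_matrix <- function(df, defs) {
  cols <- lapply(seq_len(nrow(defs)), function(i) {
    v <- defs$variable[i]
    switch(defs$class[i],
      linear = df[[v]],
      quadratic = df[[v]]^2,
      product = {
        vv <- strsplit(v, ":", fixed = TRUE)[[1]]
        df[[vv[1]]] * df[[vv[2]]]
      }
    )
  })
  m <- do.call(cbind, cols)
  colnames(m) <- defs$feature
  m
}

#' Predict suitability from a fitted maxent model
#'
#' @param object an `inv_maxent`.
#' @param newdata data frame of environmental values, or a named list of
#'   aligned `inv_raster`s covering the model's variables.
#' @param type `"logistic"` (habitat suitability index in (0,1)), `"link"`
#'   (centered score eta), or `"raw"` (relative occurrence rate, mean 1 over
#'   background).
#' @param ... unused.
#' @return numeric vector, or an `inv_raster` when `newdata` is a raster list.
#' @export
predict.inv_maxent <- function(object, newdata, type = "logistic", ...) {
  if (!is.data.frame(newdata) && is.list(newdata) &&
      inherits(newdata[[1]], "inv_raster")) {
    grid <- newdata[[1]]
    df <- tibble::as_tibble(lapply(newdata, function(l) as.vector(l$values)))
    ok <- stats::complete.cases(df)
    out <- rep(NA_real_, nrow(df))
    if (any(ok)) {
      out[ok] <- predict(object, df[ok, , drop = FALSE], type = type)
    }
    res <- const_like(grid, 0)
    res$values <- matrix(out, nrow(grid$values), ncol(grid$values))
    return(res)
  }
  Fm <- feature_matrix(as.data.frame(newdata), object$defs)
  Fm <- sweep(sweep(Fm, 2, object$center), 2, object$scale, "/")
  score <- drop(Fm %*% object$lambda)
  eta <- score - object$lse + object$entropy
  switch(type,
    link = eta,
    raw = exp(score - object$lse) * object$n_background,
    logistic = {
      t <- object$tau * exp(eta)
      t / (1 + t)
    },
    stop("unknown type: ", type, call. = FALSE)
  )
}

#' @export
print.inv_maxent <- function(x, ...) {
  cat(sprintf(
    "<inv_maxent> %d features, %d presences vs %d background; %s (%d iter, KKT %.1e)\n",
    length(x$lambda), x$n_presence, x$n_background,
    if (x$converged) "converged" else "NOT converged", x$n_iter, x$kkt))
  invisible(x)
}

#' @export
tidy.inv_maxent <- function(x, ...) {
  tibble::tibble(feature = names(x$lambda), variable = x$defs$variable,
                 class = x$defs$class, estimate = unname(x$lambda),
                 penalty = unname(x$beta))
}

#' @export
glance.inv_maxent <- function(x, ...) {
  tibble::tibble(n_presence = x$n_presence, n_background = x$n_background,
                 n_features = length(x$lambda),
                 n_nonzero = sum(x$lambda != 0), gain = x$gain,
                 converged = x$converged, n_iter = x$n_iter, kkt = x$kkt)
}

#' Rank-based AUC of presence vs background scores
#'
#' Mann-Whitney AUC: the probability that a random presence scores above a
#' random background point, ties counting one half. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores)) {
    stop("empty score set", call. = FALSE)
  }
  m <- length(presence_scores); n <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Maximum sensitivity-plus-specificity threshold
#'
#' Scans the unique training-presence scores as candidate thresholds and
#' picks the one maximizing sensitivity (fraction of presences scoring >= t)
#' plus specificity (fraction of background scoring < t); ties resolve to
#' the smallest such threshold.
#'
#' @param presence_scores training presence scores.
#' @param background_scores background scores.
#' @return list with `threshold`, `sensitivity`, `specificity` and the
#'   scanned candidate table.
#' @export
threshold_max_sss <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores)) {
    stop("empty score set", call. = FALSE)
  }
  cand <- sort(unique(presence_scores))
  sens <- vapply(cand, function(t) mean(presence_scores >= t), 0)
  spec <- vapply(cand, function(t) mean(background_scores < t), 0)
  ss <- sens + spec
  best <- which(ss >= max(ss) - 1e-12)[1]  # smallest candidate among ties
  if (length(cand) == 1 && length(unique(background_scores)) == 1 &&
      cand[1] == background_scores[1]) {
    inv_msg("degenerate all-equal scores; threshold set to that value")
  }
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best],
       candidates = tibble::tibble(threshold = cand, sensitivity = sens,
                                   specificity = spec))
}

#' Binarize a suitability raster at a threshold
#'
#' @param hsi continuous `inv_raster` of suitability scores.
#' @param threshold cells with value >= threshold become 1.
#' @param rule label recorded for provenance.
#' @return binary `inv_raster` with attributes `threshold` and `rule`.
#' @export
binarize <- function(hsi, threshold, rule = "max_sss") {
  out <- map_raster(hsi, function(v) {
    b <- (v >= threshold) + 0
    b[!is.finite(v)] <- NA_real_
    b
  })
  attr(out, "threshold") <- threshold
  attr(out, "rule") <- rule
  out
}

env_df <- function(env) {
  tibble::as_tibble(lapply(env, function(l) as.vector(l$values)))
}

env_at <- function(env, x, y) {
  grid <- env[[1]]
  rc <- cell_of(grid, x, y)
  out <- tibble::as_tibble(lapply(env, function(l) {
    v <- rep(NA_real_, length(x))
    ok <- !is.na(rc$row)
    v[ok] <- l$values[cbind(rc$row[ok], rc$col[ok])]
    v
  }))
  out
}

#' Replicated maxent fits for one species
#'
#' Runs `n_replicates` random 75/25 train/validation partitions (or
#' case-resampling bootstrap), fits each, evaluates held-out AUC, and
#' combines: the final suitability raster is the cell-wise mean of the
#' replicate logistic outputs, the final threshold the mean of the replicate
#' maximum sensitivity-plus-specificity thresholds. A full-data fit is kept
#' for variable-contribution analysis. A replicate failure is recorded; the
#' species fails only if every replicate fails.
#'
#' @param records tibble with `x`, `y` presence coordinates of one species.
#' @param env named list of aligned environmental `inv_raster`s.
#' @param background tibble of background points (`x`, `y`), e.g. from
#'   [sample_background()].
#' @param n_replicates number of replicates (default 10).
#' @param train_frac training fraction of each partition (default 0.75).
#' @param resample `"subsample"` (random 75/25 partitions) or `"bootstrap"`
#'   (case resampling, out-of-bag validation).
#' @param seed RNG seed (required).
#' @param species species label carried into reports.
#' @param ... passed to [fit_maxent()] (`classes`, `reg_multiplier`,
#'   `max_iter`, `tol`, `tau`).
#' @return an object of class `maxent_sdm` with elements `hsi`, `binary`,
#'   `threshold`, `replicates` (tibble), `model` (full-data fit), `species`.
#' @export
replicate_run <- function(records, env, background, n_replicates = 10,
                          train_frac = 0.75,
                          resample = c("subsample", "bootstrap"),
                          seed = NULL, species = "species", ...) {
  resample <- match.arg(resample)
  require_seed(seed)
  pres_env <- env_at(env, records$x, records$y)
  ok <- stats::complete.cases(pres_env)
  pres_env <- pres_env[ok, , drop = FALSE]
  if (nrow(pres_env) < 5) {
    stop("fewer than 5 presence records on valid cells", call. = FALSE)
  }
  bg_env <- env_at(env, background$x, background$y)
  bg_env <- bg_env[stats::complete.cases(bg_env), , drop = FALSE]
  n <- nrow(pres_env)
  splits <- with_seed(seed, lapply(seq_len(n_replicates), function(i) {
    if (resample == "bootstrap") {
      train <- sample(n, n, replace = TRUE)
      list(train = train, test = setdiff(seq_len(n), unique(train)))
    } else {
      train <- sample(n, max(1, round(train_frac * n)))
      list(train = train, test = setdiff(seq_len(n), train))
    }
  }))
  reps <- vector("list", n_replicates)
  hsi_sum <- NULL; hsi_min <- NULL; hsi_max <- NULL
  for (i in seq_len(n_replicates)) {
    reps[[i]] <- tryCatch({
      sp <- splits[[i]]
      fit <- fit_maxent(pres_env[sp$train, , drop = FALSE], bg_env, ...)
      bg_scores <- predict(fit, bg_env)
      tr_scores <- predict(fit, pres_env[sp$train, , drop = FALSE])
      te_scores <- if (length(sp$test)) {
        predict(fit, pres_env[sp$test, , drop = FALSE])
      } else tr_scores
      thr <- threshold_max_sss(tr_scores, bg_scores)
      hsi <- predict(fit, env)
      list(ok = TRUE, fit = fit, hsi = hsi,
           row = tibble::tibble(
             replicate = i, n_train = length(sp$train), n_test = length(sp$test),
             auc_train = evaluate_auc(tr_scores, bg_scores),
             auc_test = evaluate_auc(te_scores, bg_scores),
             threshold = thr$threshold, converged = fit$converged))
    }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  }
  good <- vapply(reps, `[[`, TRUE, "ok")
  if (!any(good)) {
    stop("all replicates failed for ", species, ": ",
         reps[[1]]$error, call. = FALSE)
  }
  if (any(!good)) {
    warning(sprintf("%d of %d replicates failed for %s",
                    sum(!good), n_replicates, species))
  }
  rows <- dplyr::bind_rows(lapply(reps[good], `[[`, "row"))
  for (r in reps[good]) {
    v <- r$hsi$values
    if (is.null(hsi_sum)) {
      hsi_sum <- v; hsi_min <- v; hsi_max <- v
    } else {
      hsi_sum <- hsi_sum + v
      hsi_min <- pmin(hsi_min, v); hsi_max <- pmax(hsi_max, v)
    }
  }
  hsi <- reps[[which(good)[1]]]$hsi
  hsi$values <- hsi_sum / sum(good)
  threshold <- mean(rows$threshold)
  full_fit <- fit_maxent(pres_env, bg_env, ...)
  structure(list(
    species = species, hsi = hsi, binary = binarize(hsi, threshold),
    threshold = threshold, replicates = rows, model = full_fit,
    hsi_range = list(min = hsi_min, max = hsi_max),
    presence_env = pres_env, background_env = bg_env,
    n_records = n
  ), class = "maxent_sdm")
}

#' @export
print.maxent_sdm <- function(x, ...) {
  cat(sprintf(
    "<maxent_sdm> %s: %d records, %d replicates, mean test AUC %.3f, threshold %.3f\n",
    x$species, x$n_records, nrow(x$replicates), mean(x$replicates$auc_test),
    x$threshold))
  invisible(x)
}

#' @export
tidy.maxent_sdm <- function(x, ...) {
  dplyr::mutate(x$replicates, species = x$species, .before = 1)
}

#' @export
glance.maxent_sdm <- function(x, ...) {
  tibble::tibble(
    species = x$species, n_records = x$n_records,
    n_replicates = nrow(x$replicates),
    auc_train = mean(x$replicates$auc_train),
    auc_test = mean(x$replicates$auc_test),
    auc_test_min = min(x$replicates$auc_test),
    auc_test_max = max(x$replicates$auc_test),
    threshold = x$threshold,
    converged_frac = mean(x$replicates$converged)
  )
}

#' Variable contributions: permutation importance and jackknife gains
#'
#' Percent contribution is computed by permutation importance: the drop in
#' training AUC when one variable's values are permuted across the
#' evaluation cells (presences and background jointly), averaged over
#' `n_perm` permutations, truncated at zero and normalized to sum 100.
#' The jackknife table reports the training gain of a model fitted with
#' only each variable and with all variables but it.
#'
#' @param sdm a `maxent_sdm` (or an `inv_maxent` plus explicit data frames).
#' @param n_perm permutations per variable.
#' @param seed RNG seed.
#' @param jackknife compute the jackknife refits (2 per variable; set FALSE
#'   to skip the refit cost when only percent contributions are needed).
#' @return list with `contributions` (tibble: variable, auc_drop,
#'   contribution_pct) and `jackknife` (tibble: variable, gain_only,
#'   gain_without, gain_full; NULL when skipped).
#' @export
variable_contributions <- function(sdm, n_perm = 3, seed = 1,
                                   jackknife = TRUE) {
  stopifnot(inherits(sdm, "maxent_sdm"))
  model <- sdm$model
  pres <- sdm$presence_env; bg <- sdm$background_env
  vars <- unique(model$defs$variable[model$defs$class != "product"])
  all_df <- dplyr::bind_rows(pres, bg)
  is_pres <- c(rep(TRUE, nrow(pres)), rep(FALSE, nrow(bg)))
  base_scores <- predict(model, all_df)
  base_auc <- evaluate_auc(base_scores[is_pres], base_scores[!is_pres])
  active <- vapply(vars, function(v) {
    any(model$lambda[model$defs$variable == v] != 0)
  }, TRUE)
  drops <- with_seed(seed, vapply(seq_along(vars), function(i) {
    v <- vars[i]
    if (!active[i]) return(0)  # variable absent from the model
    mean(vapply(seq_len(n_perm), function(p) {
      d <- all_df
      d[[v]] <- sample(d[[v]])
      s <- predict(model, d)
      max(0, base_auc - evaluate_auc(s[is_pres], s[!is_pres]))
    }, 0))
  }, 0))
  pct <- if (sum(drops) > 0) 100 * drops / sum(drops) else {
    if (length(vars) == 1) 100 else rep(0, length(vars))
  }
  jk <- if (!jackknife) NULL else dplyr::bind_rows(lapply(vars, function(v) {
    only <- tryCatch(do.call(fit_maxent, c(
      list(pres[v], bg[v]), model$settings[c("classes", "reg_multiplier",
                                             "max_iter", "tol", "tau")])),
      error = function(e) NULL)
    rest <- setdiff(vars, v)
    without <- if (length(rest)) tryCatch(do.call(fit_maxent, c(
      list(pres[rest], bg[rest]), model$settings[c("classes", "reg_multiplier",
                                                   "max_iter", "tol", "tau")])),
      error = function(e) NULL) else NULL
    tibble::tibble(variable = v,
                   gain_only = if (is.null(only)) NA_real_ else only$gain,
                   gain_without = if (is.null(without)) NA_real_ else without$gain)
  }))
  if (!is.null(jk)) jk$gain_full <- model$gain
  list(
    contributions = tibble::tibble(variable = vars, auc_drop = drops,
                                   contribution_pct = pct),
    jackknife = jk
  )
}
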