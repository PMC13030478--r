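#' Random sample of valid cells for the geographical detector
#'
#' Draws up to `n` cells uniformly without replacement from the cells that
#' are finite in the response and in every factor raster, and extracts the
#' response and factor values there.
#'
#' @param y response `inv_raster` (e.g. species richness).
#' @param factors named list of aligned factor `inv_raster`s.
#' @param n points requested (default 50000); if fewer valid cells exist,
#'   all are taken with a warning.
#' @param seed RNG seed (required).
#' @return tibble with `row`, `col`, `x`, `y_coord`, `Y`, one column per
#'   factor.
#' @export
sample_points <- function(y, factors, n = 50000, seed = NULL) {
  require_seed(seed)
  for (f in factors) stop_if_misaligned(f, y)
  ok <- is.finite(y$values)
  for (f in factors) ok <- ok & is.finite(f$values)
  valid <- which(ok)
  if (length(valid) < n) {
    warning(sprintf("only %d valid cells; sampling all of them",
                    length(valid)))
    n <- length(valid)
  }
  idx <- with_seed(seed, valid[sample.int(length(valid), n)])
  nr <- nrow(y$values)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  out <- tibble::tibble(
    row = row, col = col,
    x = y$xmin + (col - 0.5) * y$cellsize,
    y_coord = y$ymax - (row - 0.5) * y$cellsize,
    Y = y$values[idx]
  )
  for (nm in names(factors)) out[[nm]] <- factors[[nm]]$values[idx]
  out
}

#' Discretize a continuous factor into strata
#'
#' Jenks natural breaks into `k` classes by default; `manual_breaks`
#' (ascending class maxima) take precedence and are applied verbatim, the
#' route used for soil pH.
#'
#' @param values numeric vector.
#' @param method only `"jenks"` currently.
#' @param k number of classes (default 5).
#' @param manual_breaks optional ascending break vector (class maxima);
#'   produces `length(manual_breaks) + 1` classes.
#' @param seed passed to [jenks_breaks()] sampling.
#' @return integer labels 1..k with attribute `breaks`.
#' @export
discretize <- function(values, method = "jenks", k = 5, manual_breaks = NULL,
                       seed = 1) {
  if (!is.null(manual_breaks)) {
    if (is.unsorted(manual_breaks, strictly = TRUE)) {
      stop("manual breaks must be strictly ascending", call. = FALSE)
    }
    br <- manual_breaks
  } else {
    stopifnot(identical(method, "jenks"))
    if (length(unique(values[is.finite(values)])) == 1) {
      inv_msg("constant factor: single stratum")
      return(structure(rep(1L, length(values)), breaks = numeric()))
    }
    br <- as.numeric(jenks_breaks(values, k = k, seed = seed))
  }
  labs <- findInterval(values, br, left.open = TRUE) + 1L
  structure(labs, breaks = br)
}

q_decomposition <- function(y, labels) {
  ok <- is.finite(y) & !is.na(labels)
  y <- y[ok]; labels <- labels[ok]
  N <- length(y)
  pop_var <- function(v) mean((v - mean(v))^2)
  tot <- N * pop_var(y)
  groups <- split(y, labels)
  ssw <- sum(vapply(groups, function(g) length(g) * pop_var(g), 0))
  list(N = N, L = length(groups), ssw = ssw, sst = tot,
       means = vapply(groups, mean, 0),
       sizes = vapply(groups, length, 0L))
}

#' Factor detector: the q-statistic
#'
#' q = 1 - sum_h N_h sigma_h^2 / (N sigma^2) with population variances: the
#' share of the response's spatial variance explained by the stratification.
#' The p-value uses the noncentral-F transformation of q.
#'
#' @param y numeric response values at sample points.
#' @param labels integer stratum labels (same length).
#' @return tibble with `q`, `p`, `n_strata`, `n` (q is NA when the total
#'   variance is zero).
#' @export
factor_q <- function(y, labels) {
  d <- q_decomposition(y, labels)
  if (d$sst == 0) {
    return(tibble::tibble(q = NA_real_, p = NA_real_, n_strata = d$L, n = d$N))
  }
  q <- 1 - d$ssw / d$sst
  p <- if (d$L < 2 || d$N <= d$L) NA_real_ else {
    Fv <- (d$N - d$L) / (d$L - 1) * q / (1 - q)
    sigma2 <- d$sst / d$N
    ncp <- (sum(d$means^2) - sum(sqrt(d$sizes) * d$means)^2 / d$N) / sigma2
    # pf() warns about precision loss deep in the noncentral tail; the
    # p-value is then effectively 0 or 1 and the loss is immaterial
    suppressWarnings(
      stats::pf(Fv, d$L - 1, d$N - d$L, ncp = ncp, lower.tail = FALSE))
  }
  tibble::tibble(q = q, p = p, n_strata = d$L, n = d$N)
}

#' Interaction detector
#'
#' q of the cross-partition of two stratifications, categorized against the
#' single-factor q values: nonlinear weaken (q_AB < min), univariate weaken
#' (min <= q_AB <= max), bivariate enhance (max < q_AB <= qA + qB),
#' independent (q_AB = qA + qB within 1e-9), nonlinear enhance
#' (q_AB > qA + qB). Singleton cross-strata are retained with variance 0.
#'
#' @param y response values.
#' @param labels_a,labels_b stratum labels of the two factors.
#' @return tibble with `q_a`, `q_b`, `q_ab`, `category`.
#' @export
interaction_q <- function(y, labels_a, labels_b) {
  tol <- 1e-9
  qa <- factor_q(y, labels_a)$q
  qb <- factor_q(y, labels_b)$q
  cross <- as.integer(interaction(labels_a, labels_b, drop = TRUE))
  qab <- factor_q(y, cross)$q
  lo <- min(qa, qb); hi <- max(qa, qb)
  category <- if (abs(qab - (qa + qb)) <= tol) "independent"
    else if (qab > qa + qb) "nonlinear enhance"
    else if (qab > hi + tol) "bivariate enhance"
    else if (qab >= lo - tol) "univariate weaken"
    else "nonlinear weaken"
  tibble::tibble(q_a = qa, q_b = qb, q_ab = qab, category = category)
}

#' Risk detector: stratum means and pairwise Welch tests
#'
#' @param y response values.
#' @param labels stratum labels.
#' @param alpha significance level (default 0.05).
#' @return list with `means` (tibble: stratum, n, mean) and `pairs`
#'   (tibble: stratum_a, stratum_b, t, df, p, significant). Strata with
#'   fewer than 2 points appear in `means` but are excluded from testing.
#' @export
risk_detector <- function(y, labels, alpha = 0.05) {
  ok <- is.finite(y) & !is.na(labels)
  y <- y[ok]; labels <- labels[ok]
  groups <- split(y, labels)
  means <- tibble::tibble(
    stratum = names(groups),
    n = unname(vapply(groups, length, 0L)),
    mean = unname(vapply(groups, mean, 0))
  )
  testable <- names(groups)[vapply(groups, length, 0L) >= 2]
  pairs <- if (length(testable) >= 2) {
    cmb <- utils::combn(testable, 2)
    dplyr::bind_rows(lapply(seq_len(ncol(cmb)), function(i) {
      a <- groups[[cmb[1, i]]]; b <- groups[[cmb[2, i]]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        eq <- isTRUE(all.equal(mean(a), mean(b)))
        return(tibble::tibble(stratum_a = cmb[1, i], stratum_b = cmb[2, i],
                              t = if (eq) 0 else Inf, df = NA_real_,
                              p = if (eq) 1 else 0, significant = !eq))
      }
      tt <- stats::t.test(a, b)  # Welch by default
      tibble::tibble(stratum_a = cmb[1, i], stratum_b = cmb[2, i],
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value, significant = tt$p.value < alpha)
    }))
  } else {
    tibble::tibble(stratum_a = character(), stratum_b = character(),
                   t = numeric(), df = numeric(), p = numeric(),
                   significant = logical())
  }
  list(means = means, pairs = pairs)
}

#' Ecological detector
#'
#' F = \[N_A (N_B - 1) SSW_A\] / \[N_B (N_A - 1) SSW_B\] comparing whether
#' factor A's stratification of the response differs significantly from
#' B's; the decision is two-sided (either factor may be the stronger one).
#' Zero SSW in the denominator is reported significant by convention.
#'
#' @param y response values.
#' @param labels_a,labels_b stratum labels of the two factors.
#' @param alpha significance level.
#' @return tibble with `f`, `p`, `significant`.
#' @export
ecological_detector <- function(y, labels_a, labels_b, alpha = 0.05) {
  da <- q_decomposition(y, labels_a)
  db <- q_decomposition(y, labels_b)
  if (db$ssw == 0) {
    if (da$ssw == 0) {
      return(tibble::tibble(f = 1, p = 1, significant = FALSE))
    }
    inv_msg("zero SSW in denominator; reported significant by convention")
    return(tibble::tibble(f = Inf, p = 0, significant = TRUE))
  }
  Fv <- (da$N * (db$N - 1) * da$ssw) / (db$N * (da$N - 1) * db$ssw)
  p_hi <- stats::pf(Fv, da$N - 1, db$N - 1, lower.tail = FALSE)
  p <- min(1, 2 * min(p_hi, 1 - p_hi))
  tibble::tibble(f = Fv, p = p, significant = p < alpha)
}

#' Run all four geographical-detector modules
#'
#' Discretizes continuous factors (Jenks, 5 classes; `manual_breaks` entries
#' applied verbatim, the soil-pH route) and runs the factor, interaction,
#' risk and ecological detectors on a point sample.
#'
#' @param sample tibble from [sample_points()] (column `Y` plus factors).
#' @param factors character vector of factor column names (default: all
#'   non-coordinate columns).
#' @param k strata per factor (default 5).
#' @param manual_breaks named list of break vectors applied verbatim.
#' @param alpha significance level.
#' @param seed passed to the Jenks sampling.
#' @return object of class `detector_report`: list with `factor` (tibble),
#'   `interaction` (tibble), `risk` (named list), `ecological` (tibble),
#'   `labels` (tibble of stratum labels). p-values are reported raw, without
#'   multiple-testing correction (flagged in `meta`).
#' @export
geodetect <- function(sample, factors = NULL, k = 5, manual_breaks = list(),
                      alpha = 0.05, seed = 1) {
  if (is.null(factors)) {
    factors <- setdiff(names(sample), c("row", "col", "x", "y_coord", "Y"))
  }
  y <- sample$Y
  labels <- tibble::as_tibble(stats::setNames(lapply(factors, function(v) {
    discretize(sample[[v]], k = k, manual_breaks = manual_breaks[[v]],
               seed = seed)
  }), factors))
  fac <- dplyr::bind_rows(lapply(factors, function(v) {
    dplyr::mutate(factor_q(y, labels[[v]]), factor = v, .before = 1)
  }))
  inter <- if (length(factors) >= 2) {
    cmb <- utils::combn(factors, 2)
    dplyr::bind_rows(lapply(seq_len(ncol(cmb)), function(i) {
      dplyr::mutate(interaction_q(y, labels[[cmb[1, i]]], labels[[cmb[2, i]]]),
                    factor_a = cmb[1, i], factor_b = cmb[2, i], .before = 1)
    }))
  } else tibble::tibble()
  risk <- stats::setNames(lapply(factors, function(v) {
    risk_detector(y, labels[[v]], alpha = alpha)
  }), factors)
  eco <- if (length(factors) >= 2) {
    cmb <- utils::combn(factors, 2)
    dplyr::bind_rows(lapply(seq_len(ncol(cmb)), function(i) {
      dplyr::mutate(
        ecological_detector(y, labels[[cmb[1, i]]], labels[[cmb[2, i]]],
                            alpha = alpha),
        factor_a = cmb[1, i], factor_b = cmb[2, i], .before = 1)
    }))
  } else tibble::tibble()
  structure(list(factor = fac, interaction = inter, risk = risk,
                 ecological = eco, labels = labels,
                 meta = list(alpha = alpha, k = k,
                             p_adjust = "none (raw q-statistic p-values)")),
            class = "detector_report")
}

#' @export
print.detector_report <- function(x, ...) {
  cat("<detector_report>\nFactor detector:\n")
  print(dplyr::arrange(x$factor, dplyr::desc(.data$q)))
  if (nrow(x$interaction)) {
    cat("Top interactions:\n")
    print(utils::head(dplyr::arrange(x$interaction, dplyr::desc(.data$q_ab)), 5))
  }
  invisible(x)
}

#' @export
tidy.detector_report <- function(x, ...) x$factor
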