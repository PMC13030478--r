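# small fixtures built in code, shared across test files

tiny_raster <- function(values, ...) {
  inv_raster(matrix(values, nrow = sqrt(length(values))), ...)
}

# a small but complete landscape for fast end-to-end checks
small_bundle <- function(seed = 7, shape = c(60, 60), n_species = 3) {
  synthetic_landscape(shape = shape, n_species = n_species,
                      records_per_species = c(25, 60), bias_strength = 0.5,
                      spatial_range = 8, seed = seed)
}

# brute-force within-class sum of squares for a given ordered partition
ssw_of_partition <- function(values, breaks) {
  cls <- findInterval(values, breaks, left.open = TRUE) + 1
  sum(tapply(values, cls, function(g) sum((g - mean(g))^2)))
}

# exhaustive Jenks: enumerate all contiguous partitions of sorted values
jenks_exhaustive <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf; best_breaks <- NULL
  for (i in seq_len(ncol(cuts))) {
    idx <- cuts[, i]
    bounds <- c(0, idx, n)
    ssw <- 0
    for (j in seq_len(k)) {
      g <- v[(bounds[j] + 1):bounds[j + 1]]
      ssw <- ssw + sum((g - mean(g))^2)
    }
    if (ssw < best - 1e-12) { best <- ssw; best_breaks <- v[idx] }
  }
  list(ssw = best, breaks = best_breaks)
}

# brute-force q-statistic from the variance-decomposition definition
q_bruteforce <- function(y, labels) {
  N <- length(y)
  pop_var <- function(v) mean((v - mean(v))^2)
  1 - sum(vapply(split(y, labels), function(g) length(g) * pop_var(g), 0)) /
    (N * pop_var(y))
}

# naive all-pairs threat field oracle
threat_field_naive <- function(source, d_max, decay, cellsize = 1) {
  nr <- nrow(source); nc <- ncol(source)
  out <- matrix(0, nr, nc)
  src <- which(source > 0, arr.ind = TRUE)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- 0
    for (s in seq_len(nrow(src))) {
      d <- cellsize * sqrt((i - src[s, 1])^2 + (j - src[s, 2])^2)
      val <- source[src[s, 1], src[s, 2]] * decay_factor(d, d_max, decay)
      if (val > best) best <- val
    }
    out[i, j] <- best
  }
  out
}

# Moran's I by direct neighbour sums (rook contiguity)
morans_i <- function(m) {
  z <- m - mean(m)
  nr <- nrow(m); nc <- ncol(m)
  num <- 0; W <- 0
  num <- num + sum(z[-nr, ] * z[-1, ]) * 2
  W <- W + 2 * (nr - 1) * nc
  num <- num + sum(z[, -nc] * z[, -1]) * 2
  W <- W + 2 * nr * (nc - 1)
  (length(m) / W) * num / sum(z^2)
}
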