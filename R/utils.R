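# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state; seed = NULL leaves the RNG alone (callers must then seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

require_seed <- function(seed) {
  if (is.null(seed)) {
    stop("a `seed` is required: no hidden RNG state is allowed", call. = FALSE)
  }
  invisible(seed)
}

# Gaussian smoothing of a matrix by separable convolution with edge
# renormalization; sigma in cells, sigma = 0 returns the input.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth_1d <- function(mat) {
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    norm <- numeric(n)
    for (o in seq(-half, half)) {
      w <- k[o + half + 1L]
      src <- pmin(pmax(seq_len(n) + o, 1L), n)  # clamp at edges
      out <- out + w * mat[src, , drop = FALSE]
    }
    out
  }
  t(smooth_1d(t(smooth_1d(m))))
}

# 8-connected components of a logical matrix; returns integer label matrix
# (0 = background) and component sizes, deterministic scan order.
connected_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nextlab <- 0L
  sizes <- integer()
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    labels[start] <- nextlab
    count <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      count <- count + 1L
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      ni <- i + offs[, 1L]; nj <- j + offs[, 2L]
      ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
      idx <- (nj[ok] - 1L) * nr + ni[ok]
      idx <- idx[mask[idx] & labels[idx] == 0L]
      labels[idx] <- nextlab
      stack <- c(stack, idx)
    }
    sizes <- c(sizes, count)
  }
  list(labels = labels, sizes = sizes)
}

inv_msg <- function(...) {
  if (isTRUE(getOption("invrisk.quiet", TRUE))) return(invisible())
  message(sprintf(...))
}
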