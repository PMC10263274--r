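# Multiscale 3D filter bank for trainable pixel classification.
#
# Separable Gaussian filtering with reflection borders, implemented as
# shifted-slab accumulation so each axis pass is a handful of whole-array
# vector operations rather than a per-voxel loop.

gaussian_kernel <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -x / sigma^2 * g
    s <- -sum(x * k)               # response to a unit ramp
    return(k / s)
  }
  if (order == 2L) {
    k <- (x^2 / sigma^4 - 1 / sigma^2) * g
    k <- k - mean(k)               # zero response to constants
    s <- sum(x^2 * k) / 2          # response to x^2/2
    return(k / s)
  }
  stop("order must be 0, 1 or 2")
}

reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  # mirror without edge duplication: ..., 3, 2, 1 | 2, 3, ...
  i <- (i - 1L) %% (2L * (n - 1L))
  i[i >= n] <- 2L * (n - 1L) - i[i >= n]
  i + 1L
}

# Correlate `a` with kernel `k` along one axis, reflecting at the borders.
conv_axis <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(k) - 1L) %/% 2L
  out <- array(0, d)
  base <- seq_len(n)
  for (j in seq_along(k)) {
    if (k[j] == 0) next
    src <- reflect_index(base + (j - 1L - r), n)
    shifted <- switch(axis,
                      a[src, , , drop = FALSE],
                      a[, src, , drop = FALSE],
                      a[, , src, drop = FALSE])
    out <- out + k[j] * shifted
  }
  out
}

# Separable filter: per-axis derivative orders (z, y, x) at one scale.
gauss_filter_3d <- function(a, sigma, orders = c(0L, 0L, 0L)) {
  for (ax in 1:3) {
    a <- conv_axis(a, gaussian_kernel(sigma, orders[ax]), ax)
  }
  a
}

# Eigenvalues of a field of symmetric 3x3 matrices (vectorized closed form).
# Returns list(max = ..., min = ...) arrays.
sym3_eigen_range <- function(h11, h22, h33, h12, h13, h23) {
  q <- (h11 + h22 + h33) / 3
  p2 <- (h11 - q)^2 + (h22 - q)^2 + (h33 - q)^2 + 2 * (h12^2 + h13^2 + h23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > 1e-12
  b11 <- (h11 - q) / p; b22 <- (h22 - q) / p; b33 <- (h33 - q) / p
  b12 <- h12 / p; b13 <- h13 / p; b23 <- h23 / p
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  rr <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(rr) / 3
  emax <- q + 2 * p * cos(phi)
  emin <- q + 2 * p * cos(phi + 2 * pi / 3)
  emax[!ok] <- q[!ok]
  emin[!ok] <- q[!ok]
  list(max = emax, min = emin)
}

#' Compute the per-voxel feature stack
#'
#' Builds the multiscale filter bank a trainable pixel classifier is fit on:
#' raw intensity plus, at each scale sigma in `scales` (voxels), Gaussian
#' smoothing, Gaussian gradient magnitude, Laplacian of Gaussian, and the
#' largest and smallest eigenvalue of the Gaussian Hessian --- five filter
#' families x three scales + raw = 16 features. Borders are handled by
#' reflection; the computation is deterministic.
#'
#' @param volume A normalized [ts_volume()].
#' @param scales Filter scales in voxels. Default `c(0.7, 1.6, 3.5)`.
#' @return A `ts_features` object: 4D array (z, y, x, feature) with feature
#'   names on the last axis, plus the originating spacing.
#' @export
compute_features <- function(volume, scales = c(0.7, 1.6, 3.5)) {
  stopifnot(inherits(volume, "ts_volume"))
  d <- dim(volume$data)
  need <- ceiling(2 * max(scales))
  if (any(d < need)) {
    stop("volume axis lengths ", paste(d, collapse = "x"),
         " are smaller than 2 x max scale (", need, " voxels)", call. = FALSE)
  }
  a <- volume$data
  feats <- vector("list", 1L + 5L * length(scales))
  fnames <- character(length(feats))
  feats[[1]] <- a
  fnames[1] <- "raw"
  i <- 1L
  for (s in scales) {
    sm <- gauss_filter_3d(a, s, c(0L, 0L, 0L))
    gz <- gauss_filter_3d(a, s, c(1L, 0L, 0L))
    gy <- gauss_filter_3d(a, s, c(0L, 1L, 0L))
    gx <- gauss_filter_3d(a, s, c(0L, 0L, 1L))
    hzz <- gauss_filter_3d(a, s, c(2L, 0L, 0L))
    hyy <- gauss_filter_3d(a, s, c(0L, 2L, 0L))
    hxx <- gauss_filter_3d(a, s, c(0L, 0L, 2L))
    hzy <- gauss_filter_3d(a, s, c(1L, 1L, 0L))
    hzx <- gauss_filter_3d(a, s, c(1L, 0L, 1L))
    hyx <- gauss_filter_3d(a, s, c(0L, 1L, 1L))
    eig <- sym3_eigen_range(hzz, hyy, hxx, hzy, hzx, hyx)
    feats[[i + 1L]] <- sm
    feats[[i + 2L]] <- sqrt(gz^2 + gy^2 + gx^2)
    feats[[i + 3L]] <- hzz + hyy + hxx
    feats[[i + 4L]] <- eig$max
    feats[[i + 5L]] <- eig$min
    fnames[i + 1:5] <- paste0(c("gauss", "gradmag", "log", "hess_max",
                                "hess_min"), "_s", s)
    i <- i + 5L
  }
  stack <- array(unlist(feats, use.names = FALSE), dim = c(d, length(feats)))
  rm(feats)
  if (!all(is.finite(stack))) stop("non-finite feature values", call. = FALSE)
  structure(list(stack = stack, names = fnames, spacing = volume$spacing,
                 channel = volume$channel),
            class = "ts_features")
}

#' @export
print.ts_features <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<ts_features> %d x %d x %d voxels, %d features\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

# Feature matrix (n_voxels x n_features) for a set of linear voxel indices.
# Indexes the stack as a flat vector so no whole-array copy is made.
feature_matrix <- function(features, lin_idx = NULL) {
  d <- dim(features$stack)
  nvox <- prod(d[1:3])
  if (is.null(lin_idx)) lin_idx <- seq_len(nvox)
  m <- matrix(0, nrow = length(lin_idx), ncol = d[4])
  for (f in seq_len(d[4])) {
    m[, f] <- features$stack[lin_idx + (f - 1) * nvox]
  }
  colnames(m) <- features$names
  m
}
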