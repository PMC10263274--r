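#' Train a pixel classifier from brush annotations
#'
#' Fits a random-forest ensemble (100 trees by default) on the feature
#' vectors of the annotated voxels only, mirroring the interactive
#' paintbrush workflow: sparse voxels are labelled `signal` or `background`
#' and the classifier generalizes to the full volume.
#'
#' @param features A `ts_features` stack from [compute_features()].
#' @param labels Tibble/data frame of brush voxels with columns `z`, `y`,
#'   `x` (1-based voxel indices) and `class` (`"signal"`/`"background"`).
#'   Both classes must be present with at least 10 voxels each.
#' @param num_trees Trees in the ensemble.
#' @param seed Integer seed; identical seed and labels give identical
#'   predictions.
#' @return A `ts_pixel_classifier`.
#' @export
train_pixel_classifier <- function(features, labels, num_trees = 100L,
                                   seed = 1L) {
  stopifnot(inherits(features, "ts_features"))
  d <- dim(features$stack)[1:3]
  labels <- tibble::as_tibble(labels)
  req <- c("z", "y", "x", "class")
  if (!all(req %in% names(labels))) {
    stop("labels need columns z, y, x, class", call. = FALSE)
  }
  if (any(labels$z < 1 | labels$z > d[1] | labels$y < 1 | labels$y > d[2] |
            labels$x < 1 | labels$x > d[3])) {
    stop("brush coordinates outside volume bounds", call. = FALSE)
  }
  tab <- table(labels$class)
  if (length(tab) < 2L) {
    stop("brush labels contain a single class; both signal and background ",
         "must be annotated", call. = FALSE)
  }
  if (any(tab < 10L)) {
    stop("need at least 10 labelled voxels per class (got ",
         paste(names(tab), tab, sep = " = ", collapse = ", "), ")",
         call. = FALSE)
  }
  lin <- cbind(labels$z, labels$y, labels$x)
  lin <- lin[, 1] + d[1] * (lin[, 2] - 1) + d[1] * d[2] * (lin[, 3] - 1)
  x <- feature_matrix(features, lin)
  df <- data.frame(x, check.names = FALSE)
  df$.class <- factor(labels$class, levels = c("background", "signal"))
  fit <- ranger::ranger(dependent.variable.name = ".class", data = df,
                        num.trees = num_trees, probability = TRUE,
                        seed = seed, num.threads = 1L,
                        respect.unordered.factors = TRUE)
  structure(list(model = fit, feature_names = features$names,
                 num_trees = num_trees, seed = seed),
            class = "ts_pixel_classifier")
}

#' @export
print.ts_pixel_classifier <- function(x, ...) {
  cat(sprintf("<ts_pixel_classifier> %d trees on %d features (OOB error %.4f)\n",
              x$num_trees, length(x$feature_names),
              x$model$prediction.error))
  invisible(x)
}

#' Predict a per-voxel signal probability map
#'
#' Applies a trained pixel classifier to a feature stack. Prediction is
#' performed in voxel blocks to bound memory; because the classifier is
#' voxelwise, the result is independent of the block partition.
#'
#' @param classifier A `ts_pixel_classifier`.
#' @param features A `ts_features` stack computed with the same feature
#'   specification as at training.
#' @param block_voxels Voxels scored per block.
#' @return A [ts_volume()] with channel `"probability"`, values in \[0, 1\].
#' @export
predict_probability <- function(classifier, features, block_voxels = 250000L) {
  stopifnot(inherits(classifier, "ts_pixel_classifier"),
            inherits(features, "ts_features"))
  if (!identical(classifier$feature_names, features$names)) {
    stop("feature stack does not match the classifier: expected ",
         length(classifier$feature_names), " features (",
         paste(utils::head(classifier$feature_names, 3), collapse = ", "),
         ", ...)", call. = FALSE)
  }
  d <- dim(features$stack)
  nvox <- prod(d[1:3])
  prob <- numeric(nvox)
  starts <- seq(1L, nvox, by = block_voxels)
  for (s in starts) {
    idx <- s:min(s + block_voxels - 1L, nvox)
    x <- feature_matrix(features, idx)
    p <- stats::predict(classifier$model, data = data.frame(x, check.names = FALSE),
                        num.threads = 1L)$predictions
    prob[idx] <- p[, "signal"]
  }
  ts_volume(array(prob, dim = d[1:3]), spacing = features$spacing,
            channel = "probability")
}

#' Threshold a probability map and label objects blockwise
#'
#' Voxels with probability at or above `threshold` become foreground, which
#' is partitioned into connected components under 26-connectivity (6 and 18
#' also supported). Labelling runs per processing block with a union-find
#' merge across block faces, so the result is identical (up to label
#' numbering) to labelling the whole volume in one pass; the default block
#' shape (20, 500, 500) voxels in (z, y, x) mirrors blockwise processing of
#' large cleared-tissue volumes. Components smaller than `min_voxels` are
#' removed and surviving labels are renumbered consecutively from 1.
#'
#' @param prob A probability [ts_volume()] (or any volume; values compared
#'   to `threshold`).
#' @param threshold Foreground probability cutoff in (0, 1). Default 0.5.
#' @param min_voxels Minimum component size in voxels. Default 30.
#' @param block_shape Processing block in voxels (z, y, x); blocks larger
#'   than the volume degenerate to a single global pass.
#' @param connectivity 26 (default), 18 or 6.
#' @return A [ts_labels()] volume; zero foreground gives an empty labelling.
#' @export
threshold_and_label <- function(prob, threshold = 0.5, min_voxels = 30L,
                                block_shape = c(20L, 500L, 500L),
                                connectivity = 26L) {
  stopifnot(inherits(prob, "ts_volume"))
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  fg <- prob$data >= threshold
  lab <- label_components(fg, block_shape = block_shape,
                          connectivity = connectivity)
  if (min_voxels > 1L && max(lab) > 0L) {
    sizes <- tabulate(lab, nbins = max(lab))
    keep <- which(sizes >= min_voxels)
    map <- integer(max(lab))
    map[keep] <- seq_along(keep)
    nz <- lab > 0L
    lab[nz] <- map[lab[nz]]
  }
  ts_labels(lab, spacing = prob$spacing, channel = prob$channel)
}

#' Blockwise connected-component labelling of a logical mask
#'
#' @param mask 3D logical array (z, y, x).
#' @param block_shape Block extent in voxels (z, y, x).
#' @param connectivity 26, 18 or 6.
#' @return Integer 3D array of component labels, 0 = background.
#' @export
label_components <- function(mask, block_shape = c(20L, 500L, 500L),
                             connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  bs <- pmin(as.integer(block_shape), d)
  breaks <- lapply(1:3, function(ax) {
    st <- seq(1L, d[ax], by = bs[ax])
    cbind(st, pmin(st + bs[ax] - 1L, d[ax]))
  })
  lab <- array(0L, d)
  offset <- 0L
  for (bz in seq_len(nrow(breaks[[1]]))) {
    for (by in seq_len(nrow(breaks[[2]]))) {
      for (bx in seq_len(nrow(breaks[[3]]))) {
        zi <- breaks[[1]][bz, 1]:breaks[[1]][bz, 2]
        yi <- breaks[[2]][by, 1]:breaks[[2]][by, 2]
        xi <- breaks[[3]][bx, 1]:breaks[[3]][bx, 2]
        sub <- mask[zi, yi, xi, drop = FALSE]
        if (!any(sub)) next
        loc <- .cc_label_3d(sub, dim(sub), connectivity)
        nz <- loc > 0L
        loc[nz] <- loc[nz] + offset
        offset <- max(loc)
        lab[zi, yi, xi] <- loc
      }
    }
  }
  if (offset == 0L) return(lab)

  # union-find merge across block faces
  parent <- seq_len(offset)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  uf_union <- function(a, b) {
    ra <- uf_find(a); rb <- uf_find(b)
    if (ra < rb) parent[rb] <<- ra else if (rb < ra) parent[ra] <<- rb
  }
  merge_pairs <- function(pa, pb) {
    # pa, pb: 2D label slabs on opposite sides of a block face; 26- and
    # 18-connectivity couple diagonal neighbours across the face as well
    offs <- if (connectivity == 6L) {
      list(c(0L, 0L))
    } else if (connectivity == 18L) {
      list(c(0L, 0L), c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
    } else {
      as.list(data.frame(t(expand.grid(-1:1, -1:1))))
    }
    n1 <- nrow(pa); n2 <- ncol(pa)
    for (o in offs) {
      i1 <- max(1L, 1L - o[1]):min(n1, n1 - o[1])
      j1 <- max(1L, 1L - o[2]):min(n2, n2 - o[2])
      a <- pa[i1, j1, drop = FALSE]
      b <- pb[i1 + o[1], j1 + o[2], drop = FALSE]
      hit <- a > 0L & b > 0L
      if (!any(hit)) next
      prs <- unique(cbind(a[hit], b[hit]))
      for (r in seq_len(nrow(prs))) uf_union(prs[r, 1], prs[r, 2])
    }
  }
  for (ax in 1:3) {
    cuts <- breaks[[ax]][, 2]
    cuts <- cuts[cuts < d[ax]]
    for (cu in cuts) {
      sl_a <- extract_plane(lab, ax, cu)
      sl_b <- extract_plane(lab, ax, cu + 1L)
      merge_pairs(sl_a, sl_b)
    }
  }
  roots <- vapply(seq_len(offset), uf_find, integer(1))
  remap <- integer(offset)
  uroot <- unique(roots)
  remap[uroot] <- seq_along(uroot)
  final <- remap[roots]
  nz <- lab > 0L
  lab[nz] <- final[lab[nz]]
  lab
}

extract_plane <- function(a, axis, i) {
  d <- dim(a)
  p <- switch(axis,
              a[i, , , drop = FALSE],
              a[, i, , drop = FALSE],
              a[, , i, drop = FALSE])
  rest <- d[-axis]  # dropping a singleton axis preserves column-major order
  matrix(p, nrow = rest[1], ncol = rest[2])
}
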