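#' Extract per-object morphological features
#'
#' One record per labelled object: size (voxels and um^3), centroid in
#' micrometres, bounding box, intensity statistics, and the shape features
#' used by the object taxonomies --- `sphericity` (surface-to-volume proxy
#' normalized by the equivalent sphere), `bbox_fill` (fraction of the
#' bounding box occupied), `ring_score` (mean intensity of the object's
#' shell divided by the mean intensity of the spatial core region within
#' 0.5 equivalent radii of the centroid; a hollow ring scores high because
#' its core is background) and `angular_coverage` (fraction of 36 azimuthal
#' bins of the object's z-projection containing foreground; a partial ring
#' covers only part of the circle).
#'
#' @param labels A [ts_labels()] volume.
#' @param intensity The matching intensity [ts_volume()] (same shape and
#'   spacing).
#' @return A tibble with one row per object, ordered by `object_id`.
#' @export
extract_object_features <- function(labels, intensity) {
  stopifnot(inherits(labels, "ts_labels"), inherits(intensity, "ts_volume"))
  if (!identical(dim(labels$labels), dim(intensity$data))) {
    stop("labels and intensity volumes differ in shape: ",
         paste(dim(labels$labels), collapse = "x"), " vs ",
         paste(dim(intensity$data), collapse = "x"), call. = FALSE)
  }
  sp <- labels$spacing
  lab <- labels$labels
  d <- dim(lab)
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(object_id = integer(), channel = character(),
                          voxel_count = integer(), volume_um3 = numeric(),
                          cz = numeric(), cy = numeric(), cx = numeric(),
                          bbox_z0 = integer(), bbox_z1 = integer(),
                          bbox_y0 = integer(), bbox_y1 = integer(),
                          bbox_x0 = integer(), bbox_x1 = integer(),
                          mean_intensity = numeric(), max_intensity = numeric(),
                          sphericity = numeric(), bbox_fill = numeric(),
                          ring_score = numeric(), angular_coverage = numeric()))
  }
  lb <- lab[idx]
  pos <- arrayInd(idx, d)
  val <- intensity$data[idx]

  # boundary voxels: any 6-neighbour outside the object (or outside the grid)
  on_boundary <- rep(FALSE, length(idx))
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- pos
      nb[, ax] <- nb[, ax] + s
      out <- nb[, ax] < 1L | nb[, ax] > d[ax]
      nb[out, ax] <- 1L
      nb_lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      on_boundary <- on_boundary | out | lab[nb_lin] != lb
    }
  }

  vox <- tibble::tibble(
    object_id = lb,
    z = pos[, 1], y = pos[, 2], x = pos[, 3],
    uz = (pos[, 1] - 1) * sp[1], uy = (pos[, 2] - 1) * sp[2],
    ux = (pos[, 3] - 1) * sp[3],
    val = val, boundary = on_boundary)

  recs <- vox |>
    dplyr::group_by(.data$object_id) |>
    dplyr::summarise(
      voxel_count = dplyr::n(),
      cz = mean(.data$uz), cy = mean(.data$uy), cx = mean(.data$ux),
      bbox_z0 = min(.data$z), bbox_z1 = max(.data$z),
      bbox_y0 = min(.data$y), bbox_y1 = max(.data$y),
      bbox_x0 = min(.data$x), bbox_x1 = max(.data$x),
      mean_intensity = mean(.data$val), max_intensity = max(.data$val),
      n_boundary = sum(.data$boundary),
      .groups = "drop") |>
    dplyr::mutate(
      volume_um3 = .data$voxel_count * prod(sp),
      channel = labels$channel,
      req_um = (3 * .data$volume_um3 / (4 * pi))^(1 / 3),
      bbox_fill = .data$voxel_count /
        ((.data$bbox_z1 - .data$bbox_z0 + 1) *
           (.data$bbox_y1 - .data$bbox_y0 + 1) *
           (.data$bbox_x1 - .data$bbox_x0 + 1)),
      # surface proxy: boundary voxel count scaled by mean face area,
      # against the surface of the volume-equivalent sphere
      sphericity = (4 * pi * .data$req_um^2) /
        pmax(.data$n_boundary * mean(sp[c(1, 2, 3)])^2, .Machine$double.eps))

  shape <- ring_and_angle_scores(vox, recs, intensity$data, sp)
  recs |>
    dplyr::left_join(shape, by = "object_id") |>
    dplyr::select("object_id", "channel", "voxel_count", "volume_um3",
                  "cz", "cy", "cx",
                  "bbox_z0", "bbox_z1", "bbox_y0", "bbox_y1",
                  "bbox_x0", "bbox_x1",
                  "mean_intensity", "max_intensity",
                  "sphericity", "bbox_fill", "ring_score",
                  "angular_coverage") |>
    dplyr::arrange(.data$object_id)
}

# Algebraic (Kasa) circle fit: least-squares solution of
# x^2 + y^2 + D x + E y + F = 0. Falls back to the centroid for degenerate
# point sets.
kasa_circle_fit <- function(y, x) {
  n <- length(y)
  if (n < 3L || (stats::var(y) + stats::var(x)) < .Machine$double.eps) {
    return(list(cy = mean(y), cx = mean(x),
                r = max(sqrt((y - mean(y))^2 + (x - mean(x))^2), 1e-6)))
  }
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  coef <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(coef)) {
    return(list(cy = mean(y), cx = mean(x),
                r = max(sqrt((y - mean(y))^2 + (x - mean(x))^2), 1e-6)))
  }
  cx <- -coef[1] / 2
  cy <- -coef[2] / 2
  r2 <- cx^2 + cy^2 - coef[3]
  list(cy = cy, cx = cx, r = sqrt(max(r2, 1e-12)))
}

# Per-object ring score and azimuthal coverage (objects are small; loop).
ring_and_angle_scores <- function(vox, recs, img, sp) {
  d <- dim(img)
  by_obj <- split(seq_len(nrow(vox)), vox$object_id)
  out <- lapply(names(by_obj), function(id) {
    rows <- by_obj[[id]]
    rec <- recs[recs$object_id == as.integer(id), ]
    req <- rec$req_um
    ctr <- c(rec$cz, rec$cy, rec$cx)
    dzyx <- cbind(vox$uz[rows] - ctr[1], vox$uy[rows] - ctr[2],
                  vox$ux[rows] - ctr[3])
    r <- sqrt(rowSums(dzyx^2))
    # spatial core: every image voxel within 0.5*req of the centroid
    rad_vox <- pmax(ceiling(0.5 * req / sp), 1L)
    cvi <- round(ctr / sp) + 1L
    lo <- pmax(cvi - rad_vox, 1L); hi <- pmin(cvi + rad_vox, d)
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    zc <- (zi - 1) * sp[1] - ctr[1]
    yc <- (yi - 1) * sp[2] - ctr[2]
    xc <- (xi - 1) * sp[3] - ctr[3]
    q <- outer(outer(zc^2, yc^2, "+"), xc^2, "+")
    core_vals <- img[zi, yi, xi, drop = FALSE][q < (0.5 * req)^2]
    shell_vals <- vox$val[rows][r >= 0.5 * req]
    ring_score <- if (length(core_vals) == 0L || length(shell_vals) == 0L) {
      1
    } else {
      mean(shell_vals) / max(mean(core_vals), .Machine$double.eps)
    }
    # azimuthal coverage of the z-projection, measured about the underlying
    # circle centre (an incomplete circle's centroid lies inside its own
    # mass and would see nearly full azimuth); the centre is estimated by
    # iterating a Kasa circle fit on the outer-radius pixels
    proj <- unique(cbind(vox$uy[rows], vox$ux[rows]))
    py <- proj[, 1]; px <- proj[, 2]
    cy0 <- mean(py); cx0 <- mean(px)
    rfit <- max(sqrt((py - cy0)^2 + (px - cx0)^2), 1e-6)
    for (it in 1:6) {
      rho0 <- sqrt((py - cy0)^2 + (px - cx0)^2)
      sel <- rho0 >= 0.8 * max(rho0)
      if (sum(sel) < 3L) break
      fit <- kasa_circle_fit(py[sel], px[sel])
      cy0 <- fit$cy; cx0 <- fit$cx; rfit <- fit$r
    }
    dy <- py - cy0
    dx <- px - cx0
    rho <- sqrt(dy^2 + dx^2)
    usable <- rho > 0.5 * rfit
    coverage <- if (!any(usable)) {
      1
    } else {
      theta <- atan2(dy[usable], dx[usable])
      bins <- findInterval(theta, seq(-pi, pi, length.out = 37),
                           rightmost.closed = TRUE)
      length(unique(bins)) / 36
    }
    tibble::tibble(object_id = as.integer(id), ring_score = ring_score,
                   angular_coverage = coverage)
  })
  dplyr::bind_rows(out)
}

#' Object-class taxonomies
#'
#' Neuron and nucleus channels use `noise` / `single` / `cluster`; the tau
#' channel uses `noise` / `incomplete_circle` / `complete_circle` / `solid`.
#'
#' @param taxonomy `"cell"` or `"tau"`.
#' @return Character vector of class labels.
#' @export
object_taxonomy <- function(taxonomy = c("cell", "tau")) {
  taxonomy <- match.arg(taxonomy)
  switch(taxonomy,
         cell = c("noise", "single", "cluster"),
         tau = c("noise", "incomplete_circle", "complete_circle", "solid"))
}

object_feature_cols <- c("voxel_count", "volume_um3", "mean_intensity",
                         "max_intensity", "sphericity", "bbox_fill",
                         "ring_score", "angular_coverage")

#' Train a supervised object classifier
#'
#' Fits a seeded random forest on the morphological features of a manually
#' classified subset of objects (the training set), under one of the two
#' object taxonomies.
#'
#' @param records Object feature tibble from [extract_object_features()].
#' @param training Tibble with columns `object_id` and `class`; every class
#'   of the taxonomy needs at least one example.
#' @param taxonomy `"cell"` or `"tau"`.
#' @param num_trees Trees in the ensemble.
#' @param seed Integer seed.
#' @return A `ts_object_classifier`.
#' @export
train_object_classifier <- function(records, training,
                                    taxonomy = c("cell", "tau"),
                                    num_trees = 100L, seed = 1L) {
  taxonomy <- match.arg(taxonomy)
  classes <- object_taxonomy(taxonomy)
  training <- tibble::as_tibble(training)
  if (!all(training$class %in% classes)) {
    stop("unknown class in training set for taxonomy `", taxonomy, "`: ",
         paste(setdiff(training$class, classes), collapse = ", "),
         call. = FALSE)
  }
  missing_cls <- setdiff(classes, training$class)
  if (length(missing_cls) > 0) {
    stop("taxonomy classes without training examples: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  df <- dplyr::inner_join(training, records, by = "object_id")
  if (nrow(df) < nrow(training)) {
    stop("training object_ids missing from records", call. = FALSE)
  }
  x <- as.data.frame(df[, object_feature_cols])
  x$.class <- factor(df$class, levels = classes)
  fit <- ranger::ranger(dependent.variable.name = ".class", data = x,
                        num.trees = num_trees, seed = seed,
                        num.threads = 1L)
  structure(list(model = fit, taxonomy = taxonomy, classes = classes,
                 seed = seed),
            class = "ts_object_classifier")
}

#' @export
print.ts_object_classifier <- function(x, ...) {
  cat(sprintf("<ts_object_classifier> taxonomy %s (%s)\n", x$taxonomy,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Assign a class label to every object
#'
#' @param classifier A `ts_object_classifier`.
#' @param records Object feature tibble.
#' @return `records` with a `class_label` column; every object receives
#'   exactly one class.
#' @export
classify_objects <- function(classifier, records) {
  stopifnot(inherits(classifier, "ts_object_classifier"))
  if (nrow(records) == 0L) {
    return(dplyr::mutate(records, class_label = character(0)))
  }
  x <- as.data.frame(records[, object_feature_cols])
  p <- stats::predict(classifier$model, data = x, num.threads = 1L)$predictions
  dplyr::mutate(records, class_label = as.character(p))
}

#' Size and class exclusion filters
#'
#' Mirrors the exclusion rules applied before laminar statistics: objects
#' larger than `max_size` are almost always unsplit clusters and are
#' excluded, as are objects classed `noise` or `cluster`. The boundary rule
#' is strict: size exactly equal to the cutoff is kept ("above" the cutoff
#' excludes). Default cutoffs: 5000 um^3 for DAPI, 20000 um^3 for HuD
#' (merged-neuron cutoff), unbounded for AT8.
#'
#' @param records Object tibble with `volume_um3` and (optionally)
#'   `class_label`.
#' @param channel `"AT8"`, `"HuD"` or `"DAPI"`; sets the default cutoff.
#' @param max_size Size cutoff in the units of `volume_um3`; overrides the
#'   channel default.
#' @return List with tibbles `kept` and `excluded`; the two partition the
#'   input exactly.
#' @export
apply_exclusion_filters <- function(records, channel = c("AT8", "HuD", "DAPI"),
                                    max_size = NULL) {
  channel <- match.arg(channel)
  if (is.null(max_size)) {
    max_size <- switch(channel, AT8 = Inf, HuD = 20000, DAPI = 5000)
  }
  if (max_size <= 0) stop("max_size must be positive", call. = FALSE)
  bad_class <- if ("class_label" %in% names(records)) {
    records$class_label %in% c("noise", "cluster")
  } else {
    rep(FALSE, nrow(records))
  }
  drop <- records$volume_um3 > max_size | bad_class
  list(kept = records[!drop, , drop = FALSE],
       excluded = records[drop, , drop = FALSE])
}
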