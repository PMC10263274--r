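#' Construct a 3D image volume
#'
#' A `ts_volume` bundles a 3D scalar grid with its physical voxel spacing and
#' a channel identity. The axis order is fixed as (z, y, x) throughout the
#' package: the first array axis is the imaging depth z, the second is the
#' laminar axis y (pial surface at y = 1), the third is x. Voxel indices are
#' 1-based; the physical position of voxel (i, j, k) is
#' `(i - 1, j - 1, k - 1) * spacing` micrometres.
#'
#' @param data A 3D numeric array, axis order (z, y, x).
#' @param spacing Numeric length-3 vector of voxel spacing in micrometres per
#'   axis, in (z, y, x) order. All entries must be positive.
#' @param channel Channel name, one of `"AT8"`, `"HuD"`, `"DAPI"`,
#'   `"probability"`, `"layer"`.
#' @return A `ts_volume` object.
#' @examples
#' v <- ts_volume(array(0, c(4, 8, 8)), spacing = c(2, 1, 1), channel = "DAPI")
#' dim(v)
#' @export
ts_volume <- function(data, spacing = c(1, 1, 1), channel = "AT8") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array with axis order (z, y, x); got ",
         length(dim(data)), " axes", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive values (z, y, x) in micrometres",
         call. = FALSE)
  }
  channel <- match.arg(channel, c("AT8", "HuD", "DAPI", "probability", "layer"))
  if (channel == "layer") {
    vals <- unique(as.vector(data))
    if (any(vals != as.integer(vals)) || any(vals < 0) || any(vals > 6)) {
      stop("layer channel may only contain integers 0-6", call. = FALSE)
    }
  }
  structure(list(data = data, spacing = spacing, channel = channel),
            class = "ts_volume")
}

#' @export
dim.ts_volume <- function(x) dim(x$data)

#' @export
print.ts_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ts_volume> channel %s, %d x %d x %d voxels (z,y,x), spacing %s um\n",
              x$channel, d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = " x ")))
  invisible(x)
}

#' Physical volume of one voxel in cubic micrometres
#' @param x A `ts_volume` or `ts_labels` object, or a spacing vector.
#' @return Voxel volume in um^3.
#' @export
voxel_volume_um3 <- function(x) {
  sp <- if (is.numeric(x)) x else x$spacing
  prod(sp)
}

#' Construct a label volume
#'
#' Integer object identities per voxel; 0 is background. Produced by
#' [threshold_and_label()] and consumed by object feature extraction and
#' colocalization.
#'
#' @param labels 3D integer array (z, y, x) of object ids, 0 = background.
#' @param spacing Voxel spacing in micrometres (z, y, x).
#' @param channel Channel the labels were segmented from.
#' @return A `ts_labels` object.
#' @export
ts_labels <- function(labels, spacing = c(1, 1, 1), channel = "AT8") {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be >= 0", call. = FALSE)
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 channel = channel),
            class = "ts_labels")
}

#' @export
dim.ts_labels <- function(x) dim(x$labels)

#' @export
print.ts_labels <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<ts_labels> channel %s, %d x %d x %d voxels, %d objects\n",
              x$channel, d[1], d[2], d[3], max(x$labels)))
  invisible(x)
}

#' Construct a cortical layer mask
#'
#' A voxel grid whose values name the cortical layer each voxel belongs to
#' (1-6), with 0 for voxels outside any layer (background, pia, white matter).
#'
#' @param labels 3D integer array (z, y, x) with values in 0-6.
#' @param spacing Voxel spacing in micrometres (z, y, x).
#' @return A `ts_layer_mask` object with a `legend` listing the layers present.
#' @export
ts_layer_mask <- function(labels, spacing = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  bad <- labels < 0L | labels > 6L
  if (any(bad)) {
    i <- which(bad)[1]
    pos <- arrayInd(i, dim(labels))
    stop(sprintf("layer mask value %d at voxel (z=%d, y=%d, x=%d) outside 0-6",
                 labels[i], pos[1], pos[2], pos[3]), call. = FALSE)
  }
  present <- sort(setdiff(unique(as.vector(labels)), 0L))
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 legend = present),
            class = "ts_layer_mask")
}

#' @export
dim.ts_layer_mask <- function(x) dim(x$labels)

#' @export
print.ts_layer_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<ts_layer_mask> %d x %d x %d voxels, layers present: %s\n",
              d[1], d[2], d[3],
              if (length(x$legend)) paste(x$legend, collapse = ", ") else "none"))
  invisible(x)
}
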