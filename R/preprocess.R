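#' Per-plane percentile normalization
#'
#' Corrects depth-dependent intensity attenuation by rescaling every z-plane
#' independently: the plane's `low_pct` percentile maps to 0 and its
#' `high_pct` percentile to 1, with values clipped to \[0, 1\]. A plane whose
#' two percentiles coincide (zero spread) maps to all zeros. Percentiles are
#' computed over all voxels of the plane; no foreground mask exists before
#' segmentation.
#'
#' The percentile form (rather than mean matching) is robust to the sparse
#' bright objects that dominate tau planes.
#'
#' @param volume A [ts_volume()].
#' @param low_pct,high_pct Percentile anchors as fractions,
#'   `0 <= low_pct < high_pct <= 1`. Defaults 0.01 and 0.998.
#' @return A [ts_volume()] with intensities in \[0, 1\].
#' @export
normalize_planes <- function(volume, low_pct = 0.01, high_pct = 0.998) {
  stopifnot(inherits(volume, "ts_volume"))
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 1)) {
    stop("need 0 <= low_pct < high_pct <= 1", call. = FALSE)
  }
  d <- dim(volume$data)
  if (d[1] < 1L || prod(d) == 0) stop("empty volume", call. = FALSE)
  out <- volume$data
  for (z in seq_len(d[1])) {
    plane <- volume$data[z, , ]
    q <- stats::quantile(plane, c(low_pct, high_pct), names = FALSE, type = 7)
    spread <- q[2] - q[1]
    out[z, , ] <- if (spread <= 0) 0 else pmin(pmax((plane - q[1]) / spread, 0), 1)
  }
  ts_volume(out, spacing = volume$spacing, channel = volume$channel)
}

#' Block-mean downsampling to a target voxel spacing
#'
#' Downsamples by the integer ratio nearest to `target / current` on each
#' axis, averaging over non-overlapping blocks; the realized output spacing
#' is `input spacing * ratio`. Used to match pixel sizes across images
#' acquired at different magnifications.
#'
#' @param volume A [ts_volume()].
#' @param target_spacing Desired spacing (z, y, x), each at least the current
#'   spacing.
#' @param tol Maximum relative deviation of `target / current` from the
#'   nearest integer before the call fails (default 5%).
#' @return A [ts_volume()] at the realized spacing.
#' @export
downsample_to_spacing <- function(volume, target_spacing, tol = 0.05) {
  stopifnot(inherits(volume, "ts_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (any(target_spacing < volume$spacing * (1 - 1e-12))) {
    stop("target_spacing must be >= current spacing on every axis",
         call. = FALSE)
  }
  ratio_f <- target_spacing / volume$spacing
  ratio <- pmax(round(ratio_f), 1)
  off <- abs(ratio_f - ratio) / ratio
  if (any(off > tol)) {
    ax <- c("z", "y", "x")[which(off > tol)[1]]
    stop("target/current spacing ratio ", format(ratio_f[which(off > tol)[1]]),
         " on axis ", ax, " is more than ", tol * 100,
         "% away from an integer; choose an integer ratio explicitly",
         call. = FALSE)
  }
  ratio <- as.integer(ratio)
  if (all(ratio == 1L)) return(volume)
  d <- dim(volume$data)
  keep <- (d %/% ratio) * ratio
  if (any(keep < ratio)) stop("volume smaller than one block", call. = FALSE)
  arr <- volume$data[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]),
                     drop = FALSE]
  nd <- keep %/% ratio
  # fold each axis into (ratio, n) and average over the ratio dimension
  dim(arr) <- c(ratio[1], nd[1], ratio[2], nd[2], ratio[3], nd[3])
  arr <- apply(arr, c(2, 4, 6), mean)
  ts_volume(array(arr, dim = nd), spacing = volume$spacing * ratio,
            channel = volume$channel)
}
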