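#' Plot laminar statistics
#'
#' Bar panels of neuron density, non-neuron nucleus density and tau burden
#' across cortical layers 1-6.
#'
#' @param object A `ts_layer_stats` tibble from [laminar_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ts_layer_stats <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::select("layer", "neuron_density_mm3",
                  "nonneuron_nucleus_density_mm3", "burden_percent") |>
    tidyr::pivot_longer(-"layer", names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = factor(
      .data$metric,
      levels = c("neuron_density_mm3", "nonneuron_nucleus_density_mm3",
                 "burden_percent"),
      labels = c("Neuron density (mm^-3)", "Non-neuron nuclei (mm^-3)",
                 "Tau burden (%)")))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$layer), y = .data$value)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Cortical layer", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a z maximum-intensity projection of a volume with object outlines
#'
#' @param volume A [ts_volume()].
#' @param objects Optional object tibble with centroids (`cy`, `cx`, um) to
#'   mark; rows with a `ghost` or `class_label` column are coloured by it.
#' @return A ggplot object.
#' @export
plot_projection <- function(volume, objects = NULL) {
  stopifnot(inherits(volume, "ts_volume"))
  mip <- apply(volume$data, c(2, 3), max)
  df <- tibble::tibble(y = rep(seq_len(nrow(mip)), times = ncol(mip)),
                       x = rep(seq_len(ncol(mip)), each = nrow(mip)),
                       intensity = as.vector(mip))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (voxel)", y = "y (voxel)",
                  title = paste(volume$channel, "max projection")) +
    ggplot2::theme_minimal()
  if (!is.null(objects) && nrow(objects) > 0) {
    pts <- tibble::tibble(x = objects$cx / volume$spacing[3] + 1,
                          y = objects$cy / volume$spacing[2] + 1)
    p <- p + ggplot2::geom_point(data = pts, colour = "red", shape = 1,
                                 size = 2)
  }
  p
}
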