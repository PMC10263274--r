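# Voxelwise overlap counts between two label volumes, as a tibble
# (id_a, id_b, overlap). Only pairs with positive overlap appear.
overlap_table <- function(la, lb) {
  idx <- which(la > 0L & lb > 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(id_a = integer(), id_b = integer(),
                          overlap = integer()))
  }
  tibble::tibble(id_a = la[idx], id_b = lb[idx]) |>
    dplyr::count(.data$id_a, .data$id_b, name = "overlap")
}

# Best partner per id_a: maximal overlap, ties broken by lower id_b.
best_match <- function(ov) {
  ov |>
    dplyr::arrange(.data$id_a, dplyr::desc(.data$overlap), .data$id_b) |>
    dplyr::distinct(.data$id_a, .keep_all = TRUE)
}

#' Match objects across the three channels
#'
#' Links every AT8 object to the HuD object and the DAPI object with which
#' it shares the most voxels (ties broken by the lower object id), and every
#' HuD object to its best DAPI partner likewise. Overlap is counted
#' voxelwise on the segmented label masks. An AT8 object with zero overlap
#' with every HuD object and every DAPI object along its entire segmented
#' volume is flagged as a ghost tangle.
#'
#' @param at8,hud,dapi [ts_labels()] volumes sharing shape and spacing.
#' @return A tibble of colocalization records: one row per AT8 object
#'   (`at8_id`, `hud_id`, `hud_overlap`, `dapi_id`, `dapi_overlap`, `ghost`)
#'   followed by one row per HuD object without AT8 context (`hud_id`,
#'   `dapi_id`, `dapi_overlap`), distinguished by the `link` column
#'   (`"at8"` / `"hud"`).
#' @export
match_objects <- function(at8, hud, dapi) {
  stopifnot(inherits(at8, "ts_labels"), inherits(hud, "ts_labels"),
            inherits(dapi, "ts_labels"))
  dms <- list(dim(at8$labels), dim(hud$labels), dim(dapi$labels))
  if (!all(vapply(dms, identical, logical(1), dms[[1]]))) {
    stop("label volumes differ in shape", call. = FALSE)
  }
  n_at8 <- max(at8$labels, 0L)
  n_hud <- max(hud$labels, 0L)

  ah <- best_match(overlap_table(at8$labels, hud$labels))
  ad <- best_match(overlap_table(at8$labels, dapi$labels))
  hd <- best_match(overlap_table(hud$labels, dapi$labels))

  at8_rows <- tibble::tibble(at8_id = seq_len(n_at8)) |>
    dplyr::left_join(dplyr::rename(ah, at8_id = "id_a", hud_id = "id_b",
                                   hud_overlap = "overlap"),
                     by = "at8_id") |>
    dplyr::left_join(dplyr::rename(ad, at8_id = "id_a", dapi_id = "id_b",
                                   dapi_overlap = "overlap"),
                     by = "at8_id") |>
    dplyr::mutate(
      hud_overlap = dplyr::coalesce(.data$hud_overlap, 0L),
      dapi_overlap = dplyr::coalesce(.data$dapi_overlap, 0L),
      ghost = .data$hud_overlap == 0L & .data$dapi_overlap == 0L,
      link = "at8")

  hud_rows <- tibble::tibble(hud_id = seq_len(n_hud)) |>
    dplyr::left_join(dplyr::rename(hd, hud_id = "id_a", dapi_id = "id_b",
                                   dapi_overlap = "overlap"),
                     by = "hud_id") |>
    dplyr::mutate(dapi_overlap = dplyr::coalesce(.data$dapi_overlap, 0L),
                  ghost = NA, link = "hud")

  dplyr::bind_rows(at8_rows, hud_rows) |>
    dplyr::select("link", "at8_id", "hud_id", "hud_overlap",
                  "dapi_id", "dapi_overlap", "ghost")
}

#' Extract the ghost-tangle records
#'
#' A ghost tangle is an AT8 object that never colocalizes with any HuD or
#' DAPI object: both overlaps are exactly zero (strict criterion on the
#' segmented masks; a single shared voxel disqualifies).
#'
#' @param records Colocalization tibble from [match_objects()].
#' @return The subset of AT8 records with `ghost == TRUE`.
#' @export
find_ghost_tangles <- function(records) {
  dplyr::filter(records, .data$link == "at8", .data$ghost)
}

#' Assign each object its cortical layer
#'
#' The layer of an object is the mask value at its centroid voxel
#' (0 = outside any layer; such objects are excluded from laminar
#' statistics). A majority-voxel vote is available as an option for objects
#' straddling a boundary.
#'
#' @param objects Object tibble with centroid columns `cz`, `cy`, `cx`
#'   (micrometres).
#' @param mask A [ts_layer_mask()] sharing the objects' coordinate frame.
#' @param method `"centroid"` (default) or `"majority"`; majority voting
#'   needs a `labels` argument.
#' @param labels Optional [ts_labels()] volume for the majority vote.
#' @return `objects` with a `layer` column in 0-6.
#' @export
assign_layers <- function(objects, mask, method = c("centroid", "majority"),
                          labels = NULL) {
  stopifnot(inherits(mask, "ts_layer_mask"))
  method <- match.arg(method)
  d <- dim(mask$labels)
  sp <- mask$spacing
  if (nrow(objects) == 0L) return(dplyr::mutate(objects, layer = integer(0)))
  vi <- cbind(round(objects$cz / sp[1]) + 1L,
              round(objects$cy / sp[2]) + 1L,
              round(objects$cx / sp[3]) + 1L)
  if (any(vi < 1L) || any(vi[, 1] > d[1]) || any(vi[, 2] > d[2]) ||
        any(vi[, 3] > d[3])) {
    stop("object centroid outside the layer mask bounds", call. = FALSE)
  }
  if (method == "centroid") {
    lay <- mask$labels[vi]
  } else {
    if (is.null(labels)) stop("majority vote needs `labels`", call. = FALSE)
    lay <- vapply(objects$object_id, function(id) {
      vox <- which(labels$labels == id)
      if (length(vox) == 0L) return(0L)
      as.integer(names(which.max(table(mask$labels[vox]))))
    }, integer(1))
  }
  dplyr::mutate(objects, layer = as.integer(lay))
}

#' Laminar density, burden and size statistics
#'
#' Per cortical layer: neuron density (kept single HuD objects per mm^3 of
#' layer volume), non-neuron nucleus density (kept single DAPI objects not
#' matched to any HuD object), tangle count, tau burden (per-layer tangle
#' count as a percent of all layered tangles) and mean tangle size.
#'
#' @param hud_kept,dapi_kept,at8_kept Object tibbles after classification,
#'   exclusion filtering and [assign_layers()]. `hud_kept`/`dapi_kept` may
#'   be empty tibbles.
#' @param coloc Colocalization tibble from [match_objects()] (used to
#'   identify DAPI objects matched to a HuD object).
#' @param mask The [ts_layer_mask()].
#' @return A `ts_layer_stats` tibble: one row per layer 1-6 with columns
#'   `layer`, `layer_volume_mm3`, `neuron_count`, `neuron_density_mm3`,
#'   `nonneuron_nucleus_count`, `nonneuron_nucleus_density_mm3`,
#'   `tangle_count`, `burden_percent`, `mean_tangle_size_um3`.
#' @export
laminar_stats <- function(hud_kept, dapi_kept, at8_kept, coloc, mask) {
  stopifnot(inherits(mask, "ts_layer_mask"))
  voxvol_mm3 <- prod(mask$spacing) * 1e-9
  layer_vox <- tabulate(mask$labels[mask$labels > 0L], nbins = 6L)
  layer_mm3 <- layer_vox * voxvol_mm3

  count_by_layer <- function(obj) {
    if (is.null(obj) || nrow(obj) == 0L) return(integer(6))
    tabulate(obj$layer[obj$layer >= 1L & obj$layer <= 6L], nbins = 6L)
  }
  neuron_n <- count_by_layer(hud_kept)

  # DAPI objects whose nucleus is not claimed by any HuD object
  matched_dapi <- coloc |>
    dplyr::filter(.data$link == "hud", .data$dapi_overlap > 0L) |>
    dplyr::pull(.data$dapi_id)
  nonneuron <- if (nrow(dapi_kept) > 0L) {
    dplyr::filter(dapi_kept, !(.data$object_id %in% matched_dapi))
  } else {
    dapi_kept
  }
  nonneuron_n <- count_by_layer(nonneuron)

  tangle_n <- count_by_layer(at8_kept)
  for (stat_n in list(neuron_n, nonneuron_n, tangle_n)) {
    if (any(stat_n > 0L & layer_vox == 0L)) {
      stop("layer with zero mask volume contains objects; ",
           "mask and objects are inconsistent", call. = FALSE)
    }
  }
  total_tangles <- sum(tangle_n)
  burden <- if (total_tangles > 0) 100 * tangle_n / total_tangles else rep(0, 6)
  mean_size <- vapply(1:6, function(l) {
    if (nrow(at8_kept) == 0L) return(NA_real_)
    s <- at8_kept$volume_um3[at8_kept$layer == l]
    if (length(s) == 0L) NA_real_ else mean(s)
  }, numeric(1))

  dens <- function(n) ifelse(layer_mm3 > 0, n / layer_mm3, 0)
  out <- tibble::tibble(
    layer = 1:6,
    layer_volume_mm3 = layer_mm3,
    neuron_count = neuron_n,
    neuron_density_mm3 = dens(neuron_n),
    nonneuron_nucleus_count = nonneuron_n,
    nonneuron_nucleus_density_mm3 = dens(nonneuron_n),
    tangle_count = tangle_n,
    burden_percent = burden,
    mean_tangle_size_um3 = mean_size)
  class(out) <- c("ts_layer_stats", class(out))
  out
}

#' Cortical thickness by repeated line measurement
#'
#' Emulates measuring thickness by drawing lines from the pial surface into
#' the grey matter at different positions: samples `n_lines` random (z, x)
#' columns, measures the y-extent of voxels labelled 1-6 along each, and
#' returns the mean and standard error across lines. Columns hitting no
#' labelled voxel are resampled.
#'
#' @param mask A [ts_layer_mask()].
#' @param n_lines Number of lines; at least 2 (the standard error of a
#'   single line is undefined).
#' @param seed Seed for the column positions.
#' @return Tibble with `mean_um`, `se_um`, `n_lines`.
#' @export
cortical_thickness <- function(mask, n_lines = 10L, seed = 1L) {
  stopifnot(inherits(mask, "ts_layer_mask"))
  if (n_lines < 2L) {
    stop("n_lines must be at least 2 for a standard error", call. = FALSE)
  }
  d <- dim(mask$labels)
  if (!any(mask$labels > 0L)) stop("layer mask is empty", call. = FALSE)
  sp_y <- mask$spacing[2]
  with_private_seed(seed, {
    vals <- numeric(0)
    guard <- 0L
    while (length(vals) < n_lines) {
      guard <- guard + 1L
      if (guard > 1000L * n_lines) {
        stop("could not find enough columns crossing the labelled band",
             call. = FALSE)
      }
      z <- sample.int(d[1], 1L)
      x <- sample.int(d[3], 1L)
      col <- mask$labels[z, , x]
      hit <- which(col > 0L)
      if (length(hit) == 0L) next
      vals <- c(vals, (max(hit) - min(hit) + 1L) * sp_y)
    }
    tibble::tibble(mean_um = mean(vals),
                   se_um = stats::sd(vals) / sqrt(n_lines),
                   n_lines = n_lines)
  })
}
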