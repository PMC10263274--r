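#' Write a volume to HDF5
#'
#' One dataset per channel; the array is stored with axis order (z, y, x) and
#' the voxel spacing and channel name are attached as dataset attributes
#' (`spacing_um`, `channel`). Chunking uses blocks of up to (20, 500, 500)
#' voxels so that blockwise reads align with the processing block shape used
#' downstream.
#'
#' @param volume A [ts_volume()].
#' @param path Output `.h5` file. Created if missing; an existing dataset of
#'   the same name is replaced.
#' @param dataset Dataset name inside the file; defaults to the channel name.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, dataset = volume$channel) {
  stopifnot(inherits(volume, "ts_volume"))
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  if (!file.exists(path)) rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  if (rhdf5::H5Lexists(fid, dataset)) rhdf5::h5delete(fid, dataset)
  d <- dim(volume$data)
  chunk <- pmin(d, c(20L, 500L, 500L))
  rhdf5::h5createDataset(fid, dataset, dims = d, chunk = chunk,
                         storage.mode = "double")
  rhdf5::h5write(volume$data, fid, dataset)
  did <- rhdf5::H5Dopen(fid, dataset)
  rhdf5::h5writeAttribute(volume$spacing, did, "spacing_um")
  rhdf5::h5writeAttribute(volume$channel, did, "channel")
  rhdf5::H5Dclose(did)
  invisible(path)
}

#' Read a volume from HDF5
#'
#' @param path An HDF5 file containing one dataset per channel.
#' @param dataset Dataset name to read.
#' @param spacing Optional spacing override (z, y, x) in micrometres. Required
#'   when the dataset carries no `spacing_um` attribute.
#' @param channel Optional channel override; defaults to the stored `channel`
#'   attribute, falling back to the dataset name.
#' @return A [ts_volume()].
#' @export
read_volume <- function(path, dataset, spacing = NULL, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- rhdf5::h5read(path, dataset, read.attributes = TRUE)
  att <- attributes(data)
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop("dataset `", dataset, "` has ", length(dim(data)),
         " axes; a volume must have exactly 3 (z, y, x)", call. = FALSE)
  }
  if (is.null(spacing)) {
    spacing <- att[["spacing_um"]]
    if (is.null(spacing)) {
      stop("dataset `", dataset, "` carries no spacing_um attribute; ",
           "pass `spacing = c(z, y, x)` explicitly", call. = FALSE)
    }
  }
  if (is.null(channel)) {
    channel <- att[["channel"]]
    if (is.null(channel)) channel <- dataset
  }
  attributes(data) <- list(dim = dim(data))
  ts_volume(data, spacing = as.numeric(spacing), channel = as.character(channel))
}

#' Write a layer mask as a multipage TIFF
#'
#' One 8-bit page per z-plane, pixel values 0-6 (0 = outside any layer).
#'
#' @param mask A [ts_layer_mask()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_layer_mask <- function(mask, path) {
  stopifnot(inherits(mask, "ts_layer_mask"))
  d <- dim(mask$labels)
  pages <- lapply(seq_len(d[1]), function(z) {
    # tiff wants a (rows, cols) matrix in [0,1]; rows = y, cols = x
    matrix(mask$labels[z, , ] / 255, nrow = d[2], ncol = d[3])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read a layer mask from a multipage TIFF
#'
#' Pages are stacked along z; every pixel value is validated against the
#' allowed layer codes 0-6 and an out-of-range value fails with its location.
#'
#' @param path A multipage TIFF of 8-bit layer codes.
#' @param spacing Voxel spacing (z, y, x) in micrometres; TIFF carries none.
#' @return A [ts_layer_mask()].
#' @export
read_layer_mask <- function(path, spacing = c(1, 1, 1)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  ok <- vapply(pages, function(p) identical(dim(p), shp), logical(1))
  if (!all(ok)) stop("TIFF pages differ in shape", call. = FALSE)
  arr <- array(0L, c(length(pages), shp[1], shp[2]))
  for (z in seq_along(pages)) arr[z, , ] <- as.integer(pages[[z]])
  ts_layer_mask(arr, spacing = spacing)
}

#' Write / read an object or colocalization table
#'
#' Tables are written as CSV with a header and a stable column order so that
#' re-reading a written table reproduces it exactly.
#'
#' @param x A data frame.
#' @param path CSV path.
#' @return `write_table`: `path` invisibly; `read_table`: a tibble.
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read / write a JSON configuration
#'
#' @param x A named list (for writing).
#' @param path JSON path.
#' @return `read_config`: a named list; `write_config`: `path` invisibly.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_config
#' @export
write_config <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
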