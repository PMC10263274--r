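#' Configuration for a synthetic layered-cortex scene
#'
#' Defines the study conditions emulated by the generator: a six-layer
#' cortical slab (layers stacked along y, pial surface at y = 0), ellipsoidal
#' neuron somata each containing a nucleus, intracellular tau tangles hosted
#' by a subset of neurons, and extracellular ghost tangles placed away from
#' every soma and nucleus. Depth-dependent intensity attenuation and
#' Poisson + Gaussian noise emulate the imaging physics that motivates
#' per-plane normalization.
#'
#' The defaults describe an "AD-like" slab: 500 neurons across the six
#' layers, tangle probabilities peaking in layer 5 then layer 3 (the laminar
#' profile characteristic of tau pathology in the inferior temporal gyrus),
#' and 10 ghost tangles concentrated in layers 3 and 5.
#'
#' @param volume_shape Voxel grid (z, y, x). Default `c(48, 320, 160)`.
#' @param voxel_spacing Micrometres per voxel (z, y, x).
#' @param layer_fractions Six nonnegative fractions summing to 1: thickness of
#'   layers 1-6 along y.
#' @param n_neurons_per_layer Six counts of neurons to place per layer.
#' @param tangle_fraction_per_layer Six probabilities that a neuron in that
#'   layer hosts a tangle.
#' @param n_ghost_per_layer Six counts of ghost tangles per layer.
#' @param soma_radius_range Soma base radius range in micrometres.
#' @param nucleus_radius_range Nucleus radius range in micrometres; every
#'   drawn nucleus is strictly smaller than its soma.
#' @param tangle_morphology_mix Probabilities over tangle shapes
#'   `c(solid, ring, partial)`.
#' @param depth_attenuation_rate Intensity decay per micrometre of depth.
#' @param noise_model List with `poisson_scale` (photon-counting scale; 0
#'   disables shot noise) and `gaussian_sd` (read-noise sd; 0 disables).
#' @param bg_intensity,fg_intensity Pre-attenuation background / foreground
#'   intensities (arbitrary units).
#' @param min_gap Minimum surface-to-surface clearance between somata, um.
#' @param ghost_clearance Minimum clearance between a ghost tangle and any
#'   soma or nucleus, um. Kept above 2 voxels so the zero-overlap ghost
#'   criterion is unambiguous after rendering and segmentation.
#' @param seed Integer seed; the whole scene and its rendering are functions
#'   of the config alone.
#' @return A `ts_scene_config` list.
#' @export
scene_config <- function(volume_shape = c(48, 320, 160),
                         voxel_spacing = c(1, 1, 1),
                         layer_fractions = c(0.10, 0.10, 0.25, 0.10, 0.25, 0.20),
                         n_neurons_per_layer = c(30, 90, 130, 80, 110, 60),
                         tangle_fraction_per_layer = c(0.02, 0.08, 0.18, 0.08, 0.28, 0.10),
                         n_ghost_per_layer = c(0, 1, 3, 1, 4, 1),
                         soma_radius_range = c(3.5, 5.5),
                         nucleus_radius_range = c(1.8, 2.8),
                         tangle_morphology_mix = c(solid = 0.5, ring = 0.3, partial = 0.2),
                         depth_attenuation_rate = 0.01,
                         noise_model = list(poisson_scale = 1, gaussian_sd = 20),
                         bg_intensity = 100,
                         fg_intensity = 1000,
                         min_gap = 2,
                         ghost_clearance = 3,
                         seed = 1L) {
  cfg <- list(volume_shape = as.integer(volume_shape),
              voxel_spacing = as.numeric(voxel_spacing),
              layer_fractions = as.numeric(layer_fractions),
              n_neurons_per_layer = as.integer(n_neurons_per_layer),
              tangle_fraction_per_layer = as.numeric(tangle_fraction_per_layer),
              n_ghost_per_layer = as.integer(n_ghost_per_layer),
              soma_radius_range = as.numeric(soma_radius_range),
              nucleus_radius_range = as.numeric(nucleus_radius_range),
              tangle_morphology_mix = tangle_morphology_mix,
              depth_attenuation_rate = depth_attenuation_rate,
              noise_model = noise_model,
              bg_intensity = bg_intensity,
              fg_intensity = fg_intensity,
              min_gap = min_gap,
              ghost_clearance = ghost_clearance,
              seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "ts_scene_config")
}

validate_scene_config <- function(cfg) {
  if (length(cfg$volume_shape) != 3L || any(cfg$volume_shape < 1L))
    stop("volume_shape must be three positive voxel counts (z, y, x)",
         call. = FALSE)
  if (length(cfg$layer_fractions) != 6L || any(cfg$layer_fractions < 0))
    stop("layer_fractions must be six nonnegative values", call. = FALSE)
  if (abs(sum(cfg$layer_fractions) - 1) > 1e-9)
    stop("layer_fractions must sum to 1 (got ",
         format(sum(cfg$layer_fractions)), ")", call. = FALSE)
  if (any(cfg$n_neurons_per_layer < 0L) || any(cfg$n_ghost_per_layer < 0L))
    stop("object counts must be >= 0", call. = FALSE)
  if (any(cfg$tangle_fraction_per_layer < 0 | cfg$tangle_fraction_per_layer > 1))
    stop("tangle_fraction_per_layer must lie in [0, 1]", call. = FALSE)
  if (diff(cfg$soma_radius_range) < 0 || cfg$soma_radius_range[1] <= 0)
    stop("soma_radius_range must be an increasing positive range", call. = FALSE)
  if (cfg$nucleus_radius_range[1] <= 0)
    stop("nucleus_radius_range must be positive", call. = FALSE)
  invisible(cfg)
}

# Evaluate `expr` under a private RNG stream so scene generation neither
# consumes nor depends on the caller's RNG state.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# y extents (um) of each cortical layer: list of c(lo, hi), pia at y = 0.
layer_bounds_um <- function(cfg) {
  ly <- cfg$volume_shape[2] * cfg$voxel_spacing[2]
  edges <- c(0, cumsum(cfg$layer_fractions)) * ly
  lapply(1:6, function(l) c(edges[l], edges[l + 1]))
}

#' Build a ground-truth scene
#'
#' Places neurons (with interior nuclei), intracellular tangles and ghost
#' tangles by rejection sampling under a hard-core non-overlap constraint.
#' Neuron and ghost counts per layer match the config exactly; each neuron
#' hosts a tangle with the layer's tangle probability (independent Bernoulli
#' draws under the seed). Ghost tangles are guaranteed a clearance of at
#' least `ghost_clearance` micrometres from every soma and nucleus surface.
#'
#' @param config A [scene_config()].
#' @param max_retries Placement attempts per object before failing.
#' @return A `ts_scene`: list with `objects` (a tibble of planted objects)
#'   and `config`.
#' @export
build_scene <- function(config, max_retries = 1000L) {
  stopifnot(inherits(config, "ts_scene_config"))
  with_private_seed(config$seed, build_scene_impl(config, max_retries))
}

build_scene_impl <- function(cfg, max_retries) {
  sp <- cfg$voxel_spacing
  ext <- cfg$volume_shape * sp        # physical extent (z, y, x) in um
  bounds <- layer_bounds_um(cfg)

  rows <- list()
  nid <- 0L
  centres <- matrix(numeric(0), ncol = 3)  # (z, y, x) of placed somata
  soma_r <- numeric(0)                      # hard-core radius per soma

  draw_in_layer <- function(layer, r) {
    # centre must keep the full ellipsoid inside the volume in z and x,
    # and its centre inside the layer's y band
    m <- r + max(sp)
    lo <- bounds[[layer]][1]; hi <- bounds[[layer]][2]
    ylo <- max(lo, m); yhi <- min(hi, ext[2] - m)
    if (ylo >= yhi) { ylo <- lo; yhi <- hi }   # very thin layer: allow clipping in y
    if (2 * m >= ext[1] || 2 * m >= ext[3])
      stop("volume too small along z or x for an object of radius ", r,
           " um in layer ", layer, call. = FALSE)
    c(stats::runif(1, m, ext[1] - m),
      stats::runif(1, ylo, yhi),
      stats::runif(1, m, ext[3] - m))
  }

  # -- neurons + nuclei -------------------------------------------------
  for (layer in 1:6) {
    for (i in seq_len(cfg$n_neurons_per_layer[layer])) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        r0 <- stats::runif(1, cfg$soma_radius_range[1], cfg$soma_radius_range[2])
        rzyx <- r0 * stats::runif(3, 0.85, 1.15)
        rmax <- max(rzyx)
        ctr <- draw_in_layer(layer, rmax)
        if (nrow(centres) > 0) {
          d <- sqrt(colSums((t(centres) - ctr)^2))
          if (any(d < soma_r + rmax + cfg$min_gap)) next
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place neuron ", i, " in layer ", layer,
             " within ", max_retries, " retries; volume too crowded",
             call. = FALSE)
      nid <- nid + 1L
      centres <- rbind(centres, ctr)
      soma_r <- c(soma_r, rmax)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = nid, kind = "neuron",
        cz = ctr[1], cy = ctr[2], cx = ctr[3],
        rz = rzyx[1], ry = rzyx[2], rx = rzyx[3],
        true_layer = layer, host_neuron_id = NA_integer_,
        tangle_shape = NA_character_,
        wedge_start = NA_real_, wedge_coverage = NA_real_)

      # nucleus strictly inside this soma
      rmin <- min(rzyx)
      repeat {
        rn <- stats::runif(1, cfg$nucleus_radius_range[1],
                           cfg$nucleus_radius_range[2])
        if (rn < 0.8 * rmin) break
        rn <- 0.75 * rmin
        break
      }
      slack <- max(rmin - rn, 0) * 0.7
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      off <- u * stats::runif(1, 0, slack)
      nid <- nid + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = nid, kind = "nucleus",
        cz = ctr[1] + off[1], cy = ctr[2] + off[2], cx = ctr[3] + off[3],
        rz = rn, ry = rn, rx = rn,
        true_layer = layer, host_neuron_id = nid - 1L,
        tangle_shape = NA_character_,
        wedge_start = NA_real_, wedge_coverage = NA_real_)
    }
  }

  obj <- dplyr::bind_rows(rows)
  neurons <- dplyr::filter(obj, .data$kind == "neuron")

  # -- intracellular tangles (Bernoulli per neuron) ---------------------
  shapes <- names(cfg$tangle_morphology_mix)
  if (is.null(shapes)) shapes <- c("solid", "ring", "partial")
  for (k in seq_len(nrow(neurons))) {
    layer <- neurons$true_layer[k]
    if (stats::runif(1) >= cfg$tangle_fraction_per_layer[layer]) next
    rt <- 0.75 * min(neurons$rz[k], neurons$ry[k], neurons$rx[k])
    shape <- sample(shapes, 1, prob = as.numeric(cfg$tangle_morphology_mix))
    nid <- nid + 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = nid, kind = "tangle",
      cz = neurons$cz[k], cy = neurons$cy[k], cx = neurons$cx[k],
      rz = rt, ry = rt, rx = rt,
      true_layer = layer, host_neuron_id = neurons$id[k],
      tangle_shape = shape,
      wedge_start = stats::runif(1, 0, 2 * pi),
      wedge_coverage = if (shape == "partial") stats::runif(1, 0.45, 0.65) else NA_real_)
  }

  # -- ghost tangles: clearance from every soma and nucleus -------------
  nuclei <- dplyr::filter(dplyr::bind_rows(rows), .data$kind == "nucleus")
  cell_centres <- rbind(as.matrix(neurons[, c("cz", "cy", "cx")]),
                        as.matrix(nuclei[, c("cz", "cy", "cx")]))
  cell_rmax <- c(pmax(neurons$rz, neurons$ry, neurons$rx),
                 pmax(nuclei$rz, nuclei$ry, nuclei$rx))
  ghost_centres <- matrix(numeric(0), ncol = 3)
  ghost_r <- numeric(0)
  for (layer in 1:6) {
    for (i in seq_len(cfg$n_ghost_per_layer[layer])) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        rg <- 0.75 * stats::runif(1, cfg$soma_radius_range[1],
                                  cfg$soma_radius_range[2])
        ctr <- draw_in_layer(layer, rg)
        d <- sqrt(colSums((t(cell_centres) - ctr)^2))
        if (any(d < cell_rmax + rg + cfg$ghost_clearance)) next
        if (nrow(ghost_centres) > 0) {
          dg <- sqrt(colSums((t(ghost_centres) - ctr)^2))
          if (any(dg < ghost_r + rg + cfg$min_gap)) next
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place ghost tangle ", i, " in layer ", layer,
             " within ", max_retries, " retries", call. = FALSE)
      ghost_centres <- rbind(ghost_centres, ctr)
      ghost_r <- c(ghost_r, rg)
      shape <- sample(shapes, 1, prob = as.numeric(cfg$tangle_morphology_mix))
      nid <- nid + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = nid, kind = "ghost_tangle",
        cz = ctr[1], cy = ctr[2], cx = ctr[3],
        rz = rg, ry = rg, rx = rg,
        true_layer = layer, host_neuron_id = NA_integer_,
        tangle_shape = shape,
        wedge_start = stats::runif(1, 0, 2 * pi),
        wedge_coverage = if (shape == "partial") stats::runif(1, 0.45, 0.65) else NA_real_)
    }
  }

  structure(list(objects = dplyr::bind_rows(rows), config = cfg),
            class = "ts_scene")
}

#' @export
print.ts_scene <- function(x, ...) {
  counts <- table(x$objects$kind)
  cat("<ts_scene>", paste(names(counts), counts, sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' Ground-truth layer mask of a scene
#'
#' Layers are slabs orthogonal to y; voxel centres falling in the y band of
#' layer l get value l.
#'
#' @param scene A `ts_scene` (or a `ts_scene_config`).
#' @return A [ts_layer_mask()].
#' @export
scene_layer_mask <- function(scene) {
  cfg <- if (inherits(scene, "ts_scene_config")) scene else scene$config
  d <- cfg$volume_shape
  bounds <- layer_bounds_um(cfg)
  ycoord <- (seq_len(d[2]) - 1) * cfg$voxel_spacing[2]
  lab_y <- integer(d[2])
  for (l in 1:6) {
    lab_y[ycoord >= bounds[[l]][1] & ycoord < bounds[[l]][2]] <- l
  }
  lab_y[ycoord >= bounds[[6]][2]] <- 6L  # numerical edge at the last voxel
  arr <- array(rep(lab_y, each = d[1]), dim = d)
  ts_layer_mask(arr, spacing = cfg$voxel_spacing)
}

# Logical foreground mask of all objects of one channel.
# AT8 = tangles + ghost tangles (solid / ring / partial shell shapes);
# HuD = somata; DAPI = nuclei.
#' Rasterize the ground-truth foreground of one channel
#'
#' @param scene A `ts_scene`.
#' @param channel `"AT8"`, `"HuD"` or `"DAPI"`.
#' @param ids Optional subset of object ids to rasterize.
#' @return A logical 3D array (z, y, x), `TRUE` on object voxels.
#' @export
rasterize_scene <- function(scene, channel = c("AT8", "HuD", "DAPI"),
                            ids = NULL) {
  channel <- match.arg(channel)
  cfg <- scene$config
  d <- cfg$volume_shape
  sp <- cfg$voxel_spacing
  kinds <- switch(channel,
                  AT8 = c("tangle", "ghost_tangle"),
                  HuD = "neuron",
                  DAPI = "nucleus")
  obj <- dplyr::filter(scene$objects, .data$kind %in% kinds)
  if (!is.null(ids)) obj <- dplyr::filter(obj, .data$id %in% ids)
  mask <- array(FALSE, dim = d)
  for (k in seq_len(nrow(obj))) {
    mask <- stamp_object(mask, obj[k, ], sp)
  }
  mask
}

# Linear voxel indices covered by one planted object (ellipsoid, shell or
# partial shell) in a grid of dims `d` with spacing `sp`.
object_voxel_indices <- function(o, sp, d) {
  ctr <- c(o$cz, o$cy, o$cx)
  rad <- c(o$rz, o$ry, o$rx)
  lo <- pmax(floor((ctr - rad) / sp) + 1L, 1L)
  hi <- pmin(ceiling((ctr + rad) / sp) + 1L, d)
  if (any(lo > hi)) return(integer(0))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  zc <- ((zi - 1) * sp[1] - ctr[1]) / rad[1]
  yc <- ((yi - 1) * sp[2] - ctr[2]) / rad[2]
  xc <- ((xi - 1) * sp[3] - ctr[3]) / rad[3]
  rho <- sqrt(outer(outer(zc^2, yc^2, "+"), xc^2, "+"))
  shape <- o$tangle_shape
  inside <- if (is.na(shape) || shape == "solid") {
    rho <= 1
  } else {
    shell <- rho <= 1 & rho >= 0.55
    if (shape == "ring") {
      shell
    } else {  # partial: remove an azimuthal wedge of the shell (x-y plane)
      ya <- (yi - 1) * sp[2] - ctr[2]
      xa <- (xi - 1) * sp[3] - ctr[3]
      theta <- atan2(rep(ya, times = length(xa)),
                     rep(xa, each = length(ya)))    # (y, x) grid, y fastest
      rel <- (theta - o$wedge_start) %% (2 * pi)
      keep_yx <- rel <= o$wedge_coverage * 2 * pi
      keep <- aperm(array(keep_yx, dim = c(length(yi), length(xi), length(zi))),
                    c(3, 1, 2))
      shell & keep
    }
  }
  sub_idx <- which(inside)
  if (length(sub_idx) == 0L) return(integer(0))
  pos <- arrayInd(sub_idx, dim(inside))
  (lo[1] - 1L + pos[, 1]) +
    d[1] * (lo[2] - 2L + pos[, 2]) +
    d[1] * d[2] * (lo[3] - 2L + pos[, 3])
}

# Stamp one object into a logical mask.
stamp_object <- function(mask, o, sp) {
  mask[object_voxel_indices(o, sp, dim(mask))] <- TRUE
  mask
}

#' Render the multichannel volumes of a scene
#'
#' Produces the AT8, HuD and DAPI intensity volumes plus the layer mask.
#' Foreground voxels take `fg_intensity`, background `bg_intensity`; every
#' z-plane is then multiplied by `exp(-depth_attenuation_rate * z_um)`
#' (depth attenuation), and Poisson shot noise followed by additive Gaussian
#' read noise is applied. Rendering is a deterministic function of the scene
#' config (noise uses `seed + 1`).
#'
#' @param scene A `ts_scene` from [build_scene()].
#' @return List with elements `AT8`, `HuD`, `DAPI` ([ts_volume()]s),
#'   `layer_mask` ([ts_layer_mask()]) and `truth` (list of the three clean
#'   logical foreground masks).
#' @export
render_volume <- function(scene) {
  stopifnot(inherits(scene, "ts_scene"))
  cfg <- scene$config
  masks <- list(AT8 = rasterize_scene(scene, "AT8"),
                HuD = rasterize_scene(scene, "HuD"),
                DAPI = rasterize_scene(scene, "DAPI"))
  att <- exp(-cfg$depth_attenuation_rate *
               (seq_len(cfg$volume_shape[1]) - 1) * cfg$voxel_spacing[1])
  vols <- with_private_seed(cfg$seed + 1L, lapply(names(masks), function(ch) {
    img <- array(cfg$bg_intensity, dim = cfg$volume_shape)
    img[masks[[ch]]] <- cfg$fg_intensity
    img <- img * att[slice.index(img, 1)]
    s <- cfg$noise_model$poisson_scale
    if (!is.null(s) && s > 0) {
      img <- array(stats::rpois(length(img), img / s) * s, dim = dim(img))
    }
    g <- cfg$noise_model$gaussian_sd
    if (!is.null(g) && g > 0) {
      img <- img + array(stats::rnorm(length(img), 0, g), dim = dim(img))
    }
    ts_volume(img, spacing = cfg$voxel_spacing, channel = ch)
  }))
  names(vols) <- names(masks)
  c(vols, list(layer_mask = scene_layer_mask(scene), truth = masks))
}

#' Sample brush annotations from ground truth
#'
#' Emulates the sparse paintbrush labelling used to train a pixel classifier:
#' draws voxel coordinates from the clean foreground mask (class `signal`)
#' and from the complement (class `background`).
#'
#' @param scene A `ts_scene`.
#' @param channel Channel to annotate.
#' @param n_per_class Voxels to draw per class.
#' @param seed Seed for the draw.
#' @return Tibble with columns `z`, `y`, `x` (1-based voxel indices) and
#'   `class`.
#' @export
sample_brush_labels <- function(scene, channel = c("AT8", "HuD", "DAPI"),
                                n_per_class = 200L, seed = 1L) {
  channel <- match.arg(channel)
  mask <- rasterize_scene(scene, channel)
  fg <- which(mask)
  bg <- which(!mask)
  if (length(fg) < n_per_class)
    stop("channel ", channel, " has only ", length(fg),
         " foreground voxels; reduce n_per_class", call. = FALSE)
  with_private_seed(seed, {
    pick <- c(sample(fg, n_per_class), sample(bg, n_per_class))
    cls <- rep(c("signal", "background"), each = n_per_class)
    idx <- arrayInd(pick, dim(mask))
    tibble::tibble(z = idx[, 1], y = idx[, 2], x = idx[, 3], class = cls)
  })
}
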