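#' Default pipeline run configuration
#'
#' Bundles the stage parameters of a full synthetic run: the scene, the
#' per-plane normalization percentiles, the pixel-classification settings
#' and the size-exclusion cutoffs.
#'
#' @param scene A [scene_config()]; the default AD-like slab if omitted.
#' @param normalize List with `low_pct`, `high_pct`.
#' @param segment List with `threshold`, `min_voxels`, `block_shape`,
#'   `num_trees`, `n_brush` (brush voxels per class).
#' @param exclusion Named list of size cutoffs per channel (um^3).
#' @param thickness_lines Lines for the cortical-thickness measurement.
#' @return A named list, JSON-serializable via [write_config()].
#' @export
default_run_config <- function(scene = scene_config(),
                               normalize = list(low_pct = 0.01,
                                                high_pct = 0.998),
                               segment = list(threshold = 0.5,
                                              min_voxels = 30,
                                              block_shape = c(20, 500, 500),
                                              num_trees = 100,
                                              n_brush = 200),
                               exclusion = list(AT8 = Inf, HuD = 20000,
                                                DAPI = 5000),
                               thickness_lines = 10) {
  list(scene = unclass(scene), normalize = normalize, segment = segment,
       exclusion = exclusion, thickness_lines = thickness_lines)
}

#' Ghost-tangle fraction as a percent
#'
#' @param n_ghost Number of ghost tangles.
#' @param n_total Total number of tangles.
#' @param digits Decimals to round to (default 1, the reporting precision).
#' @return Percent of tangles that are ghosts.
#' @export
ghost_fraction_pct <- function(n_ghost, n_total, digits = 1) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  round(100 * n_ghost / n_total, digits)
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate, preprocess, segment, classify, colocalize, layer
#' assignment and statistics as one reproducible run: generates the scene,
#' renders and writes the three channel volumes (HDF5) and layer mask
#' (TIFF), trains a pixel classifier per channel from ground-truth-derived
#' brush labels, segments blockwise, extracts and filters objects, matches
#' objects across channels, detects ghost tangles, assigns layers and
#' computes the laminar and enrichment statistics. All randomness flows
#' from the single `seed`; reruns with the same config and seed produce
#' identical outputs.
#'
#' Synthetic scenes at the default signal-to-noise ratio contain no noise
#' or cluster objects, so the supervised object-classification stage would
#' have empty training classes; the pipeline therefore classes segmented
#' objects by their ground-truth correspondence (single / cluster / noise
#' from the number of planted objects they overlap) and notes this in the
#' report. The classifier itself is exercised on labelled feature tables
#' via [train_object_classifier()].
#'
#' @param config A list from [default_run_config()] (or a path to a JSON
#'   config).
#' @param out_dir Output directory for the run; created if missing.
#' @param seed Root seed; expanded per stage.
#' @return The run report (named list), also written to
#'   `<out_dir>/report.json`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile(),
                         seed = 1L) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate ---------------------------------------------------------
  scfg <- do.call(scene_config, c(config$scene[setdiff(names(config$scene),
                                                       "seed")],
                                  list(seed = seed)))
  scene <- stage("simulate", build_scene(scfg))
  rendered <- stage("render", render_volume(scene))
  write_table(scene$objects, file.path(out_dir, "ground_truth.csv"))
  write_layer_mask(rendered$layer_mask, file.path(out_dir, "layer_mask.tif"))
  for (ch in c("AT8", "HuD", "DAPI")) {
    write_volume(rendered[[ch]], file.path(out_dir, "channels.h5"), ch)
  }

  # -- per-channel preprocess + segment ---------------------------------
  seg <- config$segment
  channels <- c("AT8", "HuD", "DAPI")
  labels <- list()
  objects <- list()
  for (k in seq_along(channels)) {
    ch <- channels[k]
    n_fg <- sum(rendered$truth[[ch]])
    if (n_fg < 30) {
      # a channel with (essentially) no true signal: nothing to train on,
      # nothing to segment (mirrors tangle-free control tissue)
      labs <- ts_labels(array(0L, dim(rendered[[ch]]$data)),
                        spacing = scfg$voxel_spacing, channel = ch)
      labels[[ch]] <- labs
      objects[[ch]] <- truth_rule_classes(
        extract_object_features(labs, rendered[[ch]]), labs, scene, ch)
      next
    }
    norm <- stage(paste0("normalize/", ch),
                  normalize_planes(rendered[[ch]],
                                   low_pct = config$normalize$low_pct,
                                   high_pct = config$normalize$high_pct))
    feats <- stage(paste0("features/", ch), compute_features(norm))
    brush <- stage(paste0("brush/", ch),
                   sample_brush_labels(scene, ch,
                                       n_per_class = min(seg$n_brush,
                                                         floor(n_fg / 2)),
                                       seed = seed + 10L * k))
    clf <- stage(paste0("train/", ch),
                 train_pixel_classifier(feats, brush,
                                        num_trees = seg$num_trees,
                                        seed = seed + 10L * k + 1L))
    prob <- stage(paste0("predict/", ch), predict_probability(clf, feats))
    rm(feats); gc(FALSE)
    labs <- stage(paste0("label/", ch),
                  threshold_and_label(prob,
                                      threshold = seg$threshold,
                                      min_voxels = seg$min_voxels,
                                      block_shape = seg$block_shape))
    rm(prob); gc(FALSE)
    recs <- stage(paste0("objects/", ch),
                  extract_object_features(labs, rendered[[ch]]))
    recs <- truth_rule_classes(recs, labs, scene, ch)
    labels[[ch]] <- labs
    objects[[ch]] <- recs
  }

  # -- exclusion + layers + coloc ---------------------------------------
  kept <- list(); excluded <- list()
  for (ch in channels) {
    part <- apply_exclusion_filters(objects[[ch]], channel = ch,
                                    max_size = config$exclusion[[ch]])
    kept[[ch]] <- assign_layers(part$kept, rendered$layer_mask)
    excluded[[ch]] <- part$excluded
    write_table(dplyr::bind_rows(kept[[ch]],
                                 dplyr::mutate(part$excluded, layer = NA_integer_)),
                file.path(out_dir, paste0("objects_", ch, ".csv")))
  }
  coloc <- stage("coloc", match_objects(labels$AT8, labels$HuD, labels$DAPI))
  write_table(coloc, file.path(out_dir, "coloc.csv"))
  ghosts <- find_ghost_tangles(coloc)
  ghost_objects <- kept$AT8 |>
    dplyr::filter(.data$object_id %in% ghosts$at8_id)
  write_table(ghost_objects, file.path(out_dir, "ghost_tangles.csv"))

  lstats <- stage("laminar_stats",
                  laminar_stats(kept$HuD, kept$DAPI, kept$AT8, coloc,
                                rendered$layer_mask))
  write_table(lstats, file.path(out_dir, "layer_stats.csv"))
  thick <- cortical_thickness(rendered$layer_mask,
                              n_lines = config$thickness_lines,
                              seed = seed + 99L)

  # -- enrichment of ghosts in layers 3 & 5 -----------------------------
  at8_layered <- kept$AT8
  is_ghost <- at8_layered$object_id %in% ghosts$at8_id
  in35 <- at8_layered$layer %in% c(3L, 5L)
  tab <- c(a = sum(is_ghost & in35), b = sum(is_ghost & !in35),
           c = sum(!is_ghost & in35), d = sum(!is_ghost & !in35))
  enrich <- if (sum(tab[c("a", "b")]) > 0 && sum(tab[c("c", "d")]) > 0) {
    list(table = as.list(tab),
         odds_ratio = as.list(odds_ratio_ci(tab["a"], tab["b"], tab["c"],
                                            tab["d"])),
         chi_squared = as.list(chi_squared_2x2(tab["a"], tab["b"], tab["c"],
                                               tab["d"])))
  } else {
    list(table = as.list(tab), odds_ratio = NULL, chi_squared = NULL)
  }

  n_tangles <- nrow(at8_layered)
  report <- list(
    software = list(package = "tanglescape",
                    version = as.character(utils::packageVersion("tanglescape"))),
    seed = seed,
    config_hash = rlang::hash(config),
    object_classification = "ground-truth rule (no noise/cluster objects in scene)",
    counts = list(
      AT8 = list(segmented = nrow(objects$AT8), kept = nrow(kept$AT8),
                 excluded = nrow(excluded$AT8)),
      HuD = list(segmented = nrow(objects$HuD), kept = nrow(kept$HuD),
                 excluded = nrow(excluded$HuD)),
      DAPI = list(segmented = nrow(objects$DAPI), kept = nrow(kept$DAPI),
                  excluded = nrow(excluded$DAPI))),
    ghosts = list(
      count = nrow(ghosts),
      fraction_pct = if (n_tangles > 0) {
        ghost_fraction_pct(nrow(ghosts), n_tangles)
      } else NULL,
      object_ids = ghosts$at8_id,
      layers = ghost_objects$layer),
    layer_stats = lstats,
    cortical_thickness_um = list(mean = thick$mean_um, se = thick$se_um,
                                 n_lines = thick$n_lines),
    enrichment_layers_3_5 = enrich,
    planted = list(
      neurons = sum(scene$objects$kind == "neuron"),
      tangles = sum(scene$objects$kind == "tangle"),
      ghosts = sum(scene$objects$kind == "ghost_tangle")))
  write_config(report, file.path(out_dir, "report.json"))
  invisible(report)
}

# Class segmented objects by their ground-truth correspondence: the number
# of planted objects of the channel's kind that each segmented object
# overlaps (0 = noise, 1 = single, >1 = cluster); for tau, shape classes
# come from the planted tangle morphology.
truth_rule_classes <- function(recs, labs, scene, channel) {
  if (nrow(recs) == 0L) return(dplyr::mutate(recs, class_label = character(0)))
  kinds <- switch(channel, AT8 = c("tangle", "ghost_tangle"),
                  HuD = "neuron", DAPI = "nucleus")
  gt <- dplyr::filter(scene$objects, .data$kind %in% kinds)
  sp <- labs$spacing
  d <- dim(labs$labels)
  cls <- character(nrow(recs))
  # ground-truth id volume: stamp each planted object with its own id
  gt_lab <- array(0L, d)
  for (k in seq_len(nrow(gt))) {
    gt_lab[object_voxel_indices(gt[k, ], sp, d)] <- gt$id[k]
  }
  ov <- overlap_table(labs$labels, gt_lab)
  n_gt <- ov |> dplyr::count(.data$id_a, name = "n_partners")
  shape_of <- stats::setNames(gt$tangle_shape, gt$id)
  best <- best_match(ov)
  for (i in seq_len(nrow(recs))) {
    id <- recs$object_id[i]
    np <- n_gt$n_partners[n_gt$id_a == id]
    np <- if (length(np) == 0L) 0L else np
    if (channel %in% c("HuD", "DAPI")) {
      cls[i] <- if (np == 0L) "noise" else if (np == 1L) "single" else "cluster"
    } else {
      if (np == 0L) {
        cls[i] <- "noise"
      } else {
        sh <- shape_of[[as.character(best$id_b[best$id_a == id])]]
        cls[i] <- switch(sh, solid = "solid", ring = "complete_circle",
                         partial = "incomplete_circle", "solid")
      }
    }
  }
  dplyr::mutate(recs, class_label = cls)
}
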