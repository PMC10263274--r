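test_that("a 2x2x2 cube yields the closed-form record", {
  lab <- array(0L, c(6, 6, 6))
  lab[2:3, 2:3, 2:3] <- 1L
  rec <- extract_object_features(ts_labels(lab, spacing = c(1, 1, 1)),
                                 ts_volume(array(10, c(6, 6, 6))))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$voxel_count, 8L)
  expect_equal(rec$volume_um3, 8)
  # centroid of voxel indices 2:3 -> position 1.5 um on each axis
  expect_equal(c(rec$cz, rec$cy, rec$cx), c(1.5, 1.5, 1.5))
  expect_equal(rec$bbox_fill, 1)
  expect_equal(rec$mean_intensity, 10)
})

test_that("anisotropic spacing enters the physical volume", {
  lab <- array(0L, c(6, 6, 6))
  lab[2:3, 2:3, 2:3] <- 1L
  rec <- extract_object_features(ts_labels(lab, spacing = c(2, 0.5, 0.5)),
                                 ts_volume(array(1, c(6, 6, 6)),
                                           spacing = c(2, 0.5, 0.5)))
  expect_equal(rec$volume_um3, 8 * 0.5)
})

test_that("shape scores separate solid, ring and partial-ring morphologies", {
  solid <- render_single_object("solid", R = 8)
  rs <- extract_object_features(solid$labels, solid$intensity)
  expect_lte(rs$ring_score, 1)
  expect_gt(rs$angular_coverage, 0.9)

  ring <- render_single_object("ring", R = 8)
  rr <- extract_object_features(ring$labels, ring$intensity)
  expect_gt(rr$ring_score, 2)
  expect_gt(rr$angular_coverage, 0.9)

  part <- render_single_object("partial", R = 8, coverage = 0.5)
  rp <- extract_object_features(part$labels, part$intensity)
  expect_lt(abs(rp$angular_coverage - 0.5), 0.1)
})

test_that("feature extraction is invariant to label renumbering", {
  set.seed(2)
  sc <- build_scene(small_scene_config(seed = 41L))
  mask <- rasterize_scene(sc, "HuD")
  lab <- label_components(mask, block_shape = dim(mask))
  img <- ts_volume(array(100, dim(mask)) + 900 * mask, channel = "HuD")
  r1 <- extract_object_features(ts_labels(lab, channel = "HuD"), img)
  # permute labels
  perm <- sample(max(lab))
  lab2 <- lab
  lab2[lab > 0] <- perm[lab[lab > 0]]
  r2 <- extract_object_features(ts_labels(lab2, channel = "HuD"), img)
  r2_back <- r2 |>
    dplyr::mutate(object_id = match(.data$object_id, perm)) |>
    dplyr::arrange(.data$object_id)
  expect_equal(as.data.frame(r2_back), as.data.frame(r1))
})

test_that("shape mismatch between labels and intensity fails", {
  expect_error(
    extract_object_features(ts_labels(array(0L, c(4, 4, 4))),
                            ts_volume(array(0, c(4, 4, 5)))),
    "shape")
})

test_that("a separable object classifier reaches perfect held-in accuracy, deterministically", {
  set.seed(6)
  n <- 60
  recs <- tibble::tibble(
    object_id = 1:n,
    voxel_count = rep(c(50L, 5000L), each = n / 2),
    volume_um3 = as.numeric(rep(c(50, 5000), each = n / 2)) + rnorm(n),
    mean_intensity = runif(n, 500, 600),
    max_intensity = runif(n, 900, 1000),
    sphericity = runif(n, 0.7, 1),
    bbox_fill = runif(n, 0.3, 0.6),
    ring_score = runif(n, 0.8, 1.2),
    angular_coverage = 1)
  truthcls <- rep(c("single", "cluster"), each = n / 2)
  train <- tibble::tibble(object_id = c(1:20, 41:55, 21, 56),
                          class = c(rep("single", 20), rep("cluster", 15),
                                    "noise", "noise"))
  clf <- train_object_classifier(recs, train, taxonomy = "cell", seed = 3L)
  out <- classify_objects(clf, recs[c(2:19, 42:54), ])
  expect_equal(out$class_label, truthcls[c(2:19, 42:54)])
  out2 <- classify_objects(train_object_classifier(recs, train,
                                                   taxonomy = "cell",
                                                   seed = 3L),
                           recs)
  out3 <- classify_objects(train_object_classifier(recs, train,
                                                   taxonomy = "cell",
                                                   seed = 3L),
                           recs)
  expect_identical(out2$class_label, out3$class_label)
  expect_true(all(out2$class_label %in% object_taxonomy("cell")))
})

test_that("taxonomy contracts: unknown classes and missing classes fail", {
  recs <- tibble::tibble(object_id = 1:4, voxel_count = 1:4,
                         volume_um3 = 1:4, mean_intensity = 1,
                         max_intensity = 1, sphericity = 1, bbox_fill = 1,
                         ring_score = 1, angular_coverage = 1)
  expect_error(train_object_classifier(
    recs, tibble::tibble(object_id = 1:2, class = c("blob", "single")),
    taxonomy = "cell"), "unknown class")
  expect_error(train_object_classifier(
    recs, tibble::tibble(object_id = 1:2, class = c("single", "single")),
    taxonomy = "cell"), "without training examples")
})

test_that("planted tau morphologies are recovered at 90% per class", {
  # render a batch of isolated tangles of each shape at varying radius
  set.seed(31)
  shapes <- rep(c("solid", "ring", "partial"), times = 12)
  recs <- purrr::map_dfr(seq_along(shapes), function(i) {
    fix <- render_single_object(shapes[i], R = runif(1, 4.5, 7),
                                coverage = runif(1, 0.45, 0.6))
    r <- extract_object_features(fix$labels, fix$intensity)
    r$object_id <- i
    r$true_shape <- shapes[i]
    r
  })
  # small speckle objects serve as the noise class
  noise <- purrr::map_dfr(1:8, function(i) {
    lab <- array(0L, c(9, 9, 9))
    lab[5, 5, 4:5] <- 1L
    img <- array(100, c(9, 9, 9)) + array(rnorm(9^3, 0, 30), c(9, 9, 9))
    r <- extract_object_features(ts_labels(lab), ts_volume(img))
    r$object_id <- length(shapes) + i
    r$true_shape <- "noise"
    r
  })
  all_recs <- dplyr::bind_rows(recs, noise)
  cls_map <- c(solid = "solid", ring = "complete_circle",
               partial = "incomplete_circle", noise = "noise")
  all_recs$true_class <- unname(cls_map[all_recs$true_shape])
  train_idx <- c(seq(1, 36, by = 2), 37:40)   # half the tangles + 4 noise
  clf <- train_object_classifier(
    all_recs, tibble::tibble(object_id = all_recs$object_id[train_idx],
                             class = all_recs$true_class[train_idx]),
    taxonomy = "tau", seed = 9L)
  held <- all_recs[-train_idx, ]
  out <- classify_objects(clf, held)
  acc_by_class <- tapply(out$class_label == held$true_class, held$true_class,
                         mean)
  expect_true(all(acc_by_class >= 0.9))
})

test_that("exclusion filters partition records with a strict boundary", {
  recs <- tibble::tibble(object_id = 1:3, volume_um3 = c(4000, 5000, 5001),
                         class_label = "single")
  parts <- apply_exclusion_filters(recs, "DAPI")
  expect_equal(parts$kept$volume_um3, c(4000, 5000))
  expect_equal(parts$excluded$volume_um3, 5001)

  noisy <- dplyr::mutate(recs, class_label = "noise")
  parts2 <- apply_exclusion_filters(noisy, "DAPI")
  expect_equal(nrow(parts2$kept), 0)

  parts3 <- apply_exclusion_filters(recs, "AT8", max_size = Inf)
  expect_equal(nrow(parts3$excluded), 0)

  # partition property across random inputs
  set.seed(8)
  for (i in 1:5) {
    rnd <- tibble::tibble(object_id = 1:50,
                          volume_um3 = rexp(50, 1 / 4000),
                          class_label = sample(c("single", "cluster", "noise"),
                                               50, replace = TRUE))
    p <- apply_exclusion_filters(rnd, "HuD")
    expect_equal(nrow(p$kept) + nrow(p$excluded), 50)
    expect_length(intersect(p$kept$object_id, p$excluded$object_id), 0)
  }
})
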