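make_labs <- function(arr, channel = "AT8") {
  ts_labels(arr, spacing = c(1, 1, 1), channel = channel)
}

test_that("containment and argmax matching rules", {
  d <- c(8, 8, 8)
  at8 <- array(0L, d); hud <- array(0L, d); dapi <- array(0L, d)
  at8[3:4, 3:4, 3:4] <- 1L                    # 8 voxels
  hud[2:6, 2:6, 2:6] <- 1L                    # contains the tangle
  rec <- match_objects(make_labs(at8), make_labs(hud, "HuD"),
                       make_labs(dapi, "DAPI"))
  a <- dplyr::filter(rec, link == "at8")
  expect_equal(a$hud_id, 1L)
  expect_equal(a$hud_overlap, 8L)
  expect_false(a$ghost)

  # overlap 10 voxels with A, 3 with B -> links to A
  at8 <- array(0L, d); hud <- array(0L, d)
  at8[1:13 + 13] <- 1L
  at8_idx <- which(at8 == 1L)
  hud[at8_idx[1:10]] <- 1L
  hud[at8_idx[11:13]] <- 2L
  rec <- match_objects(make_labs(at8), make_labs(hud, "HuD"),
                       make_labs(dapi, "DAPI"))
  a <- dplyr::filter(rec, link == "at8")
  expect_equal(a$hud_id, 1L)
  expect_equal(a$hud_overlap, 10L)

  # exact tie broken by the lower object id
  hud[at8_idx[1:10]] <- 0L
  hud[at8_idx[1:3]] <- 5L
  hud[at8_idx[11:13]] <- 2L
  hud[hud == 5L] <- 3L
  rec <- match_objects(make_labs(at8), make_labs(hud, "HuD"),
                       make_labs(dapi, "DAPI"))
  a <- dplyr::filter(rec, link == "at8")
  expect_equal(a$hud_id, 2L)
})

test_that("the ghost criterion is strict zero overlap and flips under one-voxel mutation", {
  d <- c(8, 8, 8)
  at8 <- array(0L, d); hud <- array(0L, d); dapi <- array(0L, d)
  at8[2:3, 2:3, 2:3] <- 1L
  hud[6:8, 6:8, 6:8] <- 1L
  rec <- match_objects(make_labs(at8), make_labs(hud, "HuD"),
                       make_labs(dapi, "DAPI"))
  g <- find_ghost_tangles(rec)
  expect_equal(g$at8_id, 1L)

  # a single shared DAPI voxel disqualifies
  dapi2 <- dapi
  dapi2[2, 2, 2] <- 1L
  rec2 <- match_objects(make_labs(at8), make_labs(hud, "HuD"),
                        make_labs(dapi2, "DAPI"))
  expect_equal(nrow(find_ghost_tangles(rec2)), 0)

  # and removing it restores ghost status (mutation flips both ways)
  dapi2[2, 2, 2] <- 0L
  rec3 <- match_objects(make_labs(at8), make_labs(hud, "HuD"),
                        make_labs(dapi2, "DAPI"))
  expect_equal(nrow(find_ghost_tangles(rec3)), 1)
})

test_that("match_objects demands a shared shape", {
  expect_error(match_objects(make_labs(array(0L, c(4, 4, 4))),
                             make_labs(array(0L, c(4, 4, 5)), "HuD"),
                             make_labs(array(0L, c(4, 4, 4)), "DAPI")),
               "shape")
})

test_that("layer assignment reads the mask at the centroid and flags outside objects", {
  mask_arr <- array(0L, c(4, 12, 4))
  mask_arr[, 3:6, ] <- 3L
  mask_arr[, 7:12, ] <- 5L
  mask <- ts_layer_mask(mask_arr)
  obj <- tibble::tibble(object_id = 1:3,
                        cz = c(1, 1, 1), cy = c(3, 9, 0), cx = c(1, 1, 1))
  out <- assign_layers(obj, mask)
  expect_equal(out$layer, c(3L, 5L, 0L))
  far <- tibble::tibble(object_id = 1, cz = 1, cy = 50, cx = 1)
  expect_error(assign_layers(far, mask), "bounds")
})

test_that("laminar densities and burden follow the arithmetic", {
  # layer 1: 125 voxels at (100 um)^3 = 0.125 mm^3, holding 250 neurons
  mask_arr <- array(0L, c(5, 10, 5))
  mask_arr[, 1:5, ] <- 1L
  mask_arr[, 6:10, ] <- 2L
  mask <- ts_layer_mask(mask_arr, spacing = c(100, 100, 100))
  neurons <- tibble::tibble(object_id = 1:250, layer = 1L,
                            volume_um3 = 500, class_label = "single")
  empty <- neurons[0, ]
  coloc <- tibble::tibble(link = character(), at8_id = integer(),
                          hud_id = integer(), hud_overlap = integer(),
                          dapi_id = integer(), dapi_overlap = integer(),
                          ghost = logical())
  ls <- laminar_stats(neurons, empty, empty, coloc, mask)
  expect_equal(ls$neuron_density_mm3[1], 250 / 0.125)
  expect_equal(ls$neuron_count[2], 0L)

  # burden: counts (1,4,30,5,50,10) -> layer 5 is 50%
  tangles <- tibble::tibble(
    object_id = seq_len(100),
    layer = rep(1:6, times = c(1, 4, 30, 5, 50, 10)),
    volume_um3 = 200, class_label = "solid")
  mask6 <- ts_layer_mask(array(rep(1:6, each = 4), c(2, 12, 2)))
  ls2 <- laminar_stats(empty, empty, tangles, coloc, mask6)
  expect_equal(ls2$burden_percent[5], 50)
  expect_equal(sum(ls2$burden_percent), 100)
  expect_equal(ls2$tangle_count, c(1L, 4L, 30L, 5L, 50L, 10L))
})

test_that("non-neuron nuclei are DAPI singles unmatched to any HuD object", {
  mask <- ts_layer_mask(array(1L, c(2, 4, 2)))
  dapi <- tibble::tibble(object_id = 1:4, layer = 1L, volume_um3 = 100,
                         class_label = "single")
  coloc <- tibble::tibble(
    link = c("hud", "hud"), at8_id = NA_integer_,
    hud_id = c(1L, 2L), hud_overlap = 0L,
    dapi_id = c(1L, 3L), dapi_overlap = c(40L, 0L),
    ghost = NA)
  ls <- laminar_stats(dapi[0, ], dapi, dapi[0, ], coloc, mask)
  # dapi 1 matched (overlap 40); dapi 3 unmatched (overlap 0); 2 and 4 untouched
  expect_equal(ls$nonneuron_nucleus_count[1], 3L)
})

test_that("cortical thickness: constant slab, wedge bounds, and contracts", {
  slab <- array(0L, c(6, 40, 6))
  slab[, 11:30, ] <- 2L           # 20 voxels x 100 um = 2000 um everywhere
  mask <- ts_layer_mask(slab, spacing = c(100, 100, 100))
  th <- cortical_thickness(mask, n_lines = 10, seed = 4L)
  expect_equal(th$mean_um, 2000)
  expect_equal(th$se_um, 0)

  expect_error(cortical_thickness(mask, n_lines = 1), "at least 2")
  expect_error(cortical_thickness(ts_layer_mask(array(0L, c(4, 4, 4)))),
               "empty")

  # wedge varying linearly 1800 -> 2200 um along x
  wedge <- array(0L, c(4, 250, 100))
  for (x in 1:100) {
    n <- round(180 + (x - 1) * (220 - 180) / 99)
    wedge[, 1:n, x] <- 3L
  }
  wm <- ts_layer_mask(wedge, spacing = c(10, 10, 10))
  tw <- cortical_thickness(wm, n_lines = 25, seed = 9L)
  expect_gt(tw$mean_um, 1800)
  expect_lt(tw$mean_um, 2200)
  expect_gt(tw$se_um, 0)
})

test_that("per-layer tangle counts plus layer-0 conserve the kept AT8 total", {
  set.seed(13)
  mask_arr <- array(0L, c(3, 24, 3))
  mask_arr[, 5:22, ] <- rep(1:6, each = 3)
  mask <- ts_layer_mask(mask_arr)
  n <- 40
  at8 <- tibble::tibble(
    object_id = 1:n,
    cz = runif(n, 0, 2), cy = runif(n, 0, 23), cx = runif(n, 0, 2),
    volume_um3 = 100, class_label = "solid")
  at8 <- assign_layers(at8, mask)
  empty <- at8[0, ]
  coloc <- tibble::tibble(link = character(), at8_id = integer(),
                          hud_id = integer(), hud_overlap = integer(),
                          dapi_id = integer(), dapi_overlap = integer(),
                          ghost = logical())
  ls <- laminar_stats(empty, empty, at8, coloc, mask)
  expect_equal(sum(ls$tangle_count) + sum(at8$layer == 0L), n)
})

test_that("planted intracellular tangles link to their true host neurons", {
  sc <- build_scene(small_scene_config(seed = 55L))
  d <- sc$config$volume_shape
  sp <- sc$config$voxel_spacing
  stamp_kind <- function(kinds) {
    gt <- sc$objects[sc$objects$kind %in% kinds, ]
    arr <- array(0L, d)
    for (k in seq_len(nrow(gt))) {
      arr[tanglescape:::object_voxel_indices(gt[k, ], sp, d)] <- gt$id[k]
    }
    arr
  }
  at8 <- stamp_kind(c("tangle", "ghost_tangle"))
  hud <- stamp_kind("neuron")
  dapi <- stamp_kind("nucleus")
  # compress ids to consecutive labels, remembering the mapping
  compress <- function(a) {
    ids <- sort(unique(a[a > 0]))
    out <- a
    out[a > 0] <- match(a[a > 0], ids)
    list(lab = out, ids = ids)
  }
  ca <- compress(at8); ch <- compress(hud); cd <- compress(dapi)
  rec <- match_objects(make_labs(ca$lab), make_labs(ch$lab, "HuD"),
                       make_labs(cd$lab, "DAPI"))
  tangles <- sc$objects[sc$objects$kind == "tangle", ]
  a8 <- dplyr::filter(rec, link == "at8")
  for (i in seq_len(nrow(tangles))) {
    at8_label <- match(tangles$id[i], ca$ids)
    linked_hud <- a8$hud_id[a8$at8_id == at8_label]
    expect_equal(ch$ids[linked_hud], tangles$host_neuron_id[i])
  }
  # all and only planted ghosts are returned
  ghosts <- sc$objects[sc$objects$kind == "ghost_tangle", ]
  got <- sort(ca$ids[find_ghost_tangles(rec)$at8_id])
  expect_equal(got, sort(ghosts$id))
})
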