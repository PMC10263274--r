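# Shared fixtures: tiny scenes, independent oracles, partition helpers.

# A small, quick scene used across modules.
small_scene_config <- function(seed = 11L, ...) {
  args <- list(
    volume_shape = c(24L, 96L, 64L),
    layer_fractions = c(0.10, 0.10, 0.25, 0.10, 0.25, 0.20),
    n_neurons_per_layer = c(2, 4, 8, 4, 8, 4),
    tangle_fraction_per_layer = c(0, 0.3, 0.5, 0.3, 0.5, 0.3),
    n_ghost_per_layer = c(0, 0, 1, 0, 1, 0),
    seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(scene_config, args)
}

# Independent 26-connected components oracle built on igraph.
cc_oracle_igraph <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lin <- which(mask)
  out <- array(0L, d)
  if (length(lin) == 0L) return(out)
  id <- array(0L, d)
  id[lin] <- seq_along(lin)
  pos <- arrayInd(lin, d)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  manh <- rowSums(abs(offs))
  keep <- manh > 0 & switch(as.character(connectivity),
                            "6" = manh <= 1, "18" = manh <= 2, manh <= 3)
  offs <- offs[keep, , drop = FALSE]
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nid <- id[nb[ok, , drop = FALSE]]
    sel <- nid > 0L
    if (any(sel)) edges[[length(edges) + 1L]] <- cbind(which(ok)[sel], nid[sel])
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (length(edges)) {
    e <- unique(do.call(rbind, edges))
    g <- igraph::add_edges(g, t(e))
  }
  out[lin] <- as.integer(igraph::components(g)$membership)
  out
}

# TRUE when two labelings define the same partition of the same foreground.
same_partition <- function(l1, l2) {
  m1 <- l1 > 0L
  if (!identical(m1, l2 > 0L)) return(FALSE)
  f1 <- l1[m1]; f2 <- l2[m1]
  one_to_one <- function(a, b) {
    all(vapply(split(b, a), function(v) length(unique(v)) == 1L, logical(1)))
  }
  one_to_one(f1, f2) && one_to_one(f2, f1)
}

# Object tibble for a single rendered tangle-like object (label volume +
# intensity volume), used for shape-feature audits.
render_single_object <- function(shape, R = 6, dimv = c(33L, 33L, 33L),
                                 fg = 1000, bg = 100, coverage = 0.5) {
  ctr <- (dimv - 1) / 2
  o <- tibble::tibble(cz = ctr[1], cy = ctr[2], cx = ctr[3],
                      rz = R, ry = R, rx = R,
                      tangle_shape = shape,
                      wedge_start = 0, wedge_coverage = coverage)
  mask <- array(FALSE, dimv)
  mask <- tanglescape:::stamp_object(mask, o, c(1, 1, 1))
  img <- array(bg, dimv)
  img[mask] <- fg
  list(labels = ts_labels(array(as.integer(mask), dimv)),
       intensity = ts_volume(img, channel = "AT8"),
       mask = mask, centre = ctr, R = R)
}
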