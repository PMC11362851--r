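full_stages <- function(g, params = gmsa_space_params()) {
  dag <- gmsa_build_dag(g)
  proper <- gmsa_make_proper(dag, gmsa_assign_layers(dag))
  bs <- gmsa_block_sets(proper)
  sift <- gmsa_global_sift(bs)
  tracks <- gmsa_assign_tracks(bs, sift)
  routes <- gmsa_route_edges(bs, tracks, params)
  geom <- gmsa_final_geometry(g, proper$layer, tracks, routes)
  list(dag = dag, proper = proper, bs = bs, sift = sift, tracks = tracks,
       routes = routes, geom = geom)
}

test_that("collapsing dummies restores one drawable edge per DAG edge", {
  for (k in 1:20) {
    g <- gmsa_synth(n_guide_vertices = sample(5:15, 1),
                    n_comparative = sample(0:4, 1), seed = 13000 + k)
    st <- full_stages(g)
    expect_equal(nrow(st$routes$drawable), nrow(st$dag$edges))
    # long edges carry the track of their dummy block as route elevation
    long <- st$routes$drawable[st$routes$drawable$span > 1L, ]
    for (m in seq_len(nrow(long))) {
      chain <- st$proper$chains[[long$key[m]]]
      expect_equal(long$route_track[m], unname(st$tracks$y[chain[1]]))
    }
  }
})

test_that("bundling partitions tuples by direction into at most two bundles", {
  d <- tibble::tibble(key = "e", from = "u", to = "v", span = 1L,
                      gap_first = 0L, gap_last = 0L, route_track = NA_integer_,
                      tuples = list(tibble::tibble(
                        direction = c("forward", "forward", "backward"),
                        sequence = c("s1", "s2", "s3"))))
  b <- gmsa_bundle_edges(d, gmsa_space_params())
  expect_equal(nrow(b), 2)
  expect_setequal(b$direction, c("forward", "backward"))
  expect_equal(sum(b$n_members), 3)
  expect_equal(b$width[b$direction == "forward"], 2)

  d$tuples <- list(tibble::tibble(direction = "forward", sequence = "s1"))
  b1 <- gmsa_bundle_edges(d, gmsa_space_params())
  expect_equal(nrow(b1), 1)
  expect_equal(b1$width, 1)
})

test_that("connection points land in the correct vertex zones", {
  # x below the guide (or above): its edges leave/enter through up/down
  # zones; straight guide edges stay centered
  g <- mk_graph(c("a", "b", "c"), c("a", "x", "c"))
  st <- full_stages(g)
  ends <- st$routes$ends
  tx <- st$tracks$y[["x"]]
  side <- if (tx > 0) "down" else "up"
  e_ax <- ends[ends$key == gmsalayout:::edge_key("a", "x") &
               ends$at == "from", ]
  expect_equal(e_ax$zone, side)
  e_ab <- ends[ends$key == gmsalayout:::edge_key("a", "b"), ]
  expect_equal(unique(e_ab$zone), "straight")
  # straight bundles are centered at the vertex midpoint
  expect_equal(unique(abs(e_ab$dist)), 0)
})

test_that("facing down-edges share rank space, left vertex first", {
  # u and w sit on the guide; both send an edge down to the same inserted
  # vertex region: the left vertex's connection is allocated before the
  # right vertex's, which is pushed one rank deeper
  g <- mk_graph(c("a", "b", "c"), c("a", "x", "c"), c("a", "y", "c"))
  st <- full_stages(g)
  ends <- st$routes$ends
  below <- ends[ends$zone == "down" & ends$gap == 0, ]
  if (nrow(below) >= 2) {
    from_dist <- below$dist[below$at == "from"]
    to_dist <- below$dist[below$at == "to"]
    if (length(from_dist) && length(to_dist)) {
      expect_true(min(to_dist) > min(from_dist))
    }
  }
  expect_gt(nrow(ends), 0)
})

test_that("every vertical segment has a unique slot per inter-layer gap", {
  for (k in 1:20) {
    g <- gmsa_synth(n_guide_vertices = sample(5:15, 1),
                    n_comparative = sample(1:5, 1), seed = 14000 + k)
    st <- full_stages(g)
    sl <- st$routes$slots
    if (nrow(sl) == 0) next
    for (gp in unique(sl$gap)) {
      r <- sl$rank[sl$gap == gp]
      expect_equal(sort(r), seq_along(r) - 1L)
    }
    # exact coordinate scan over the rendered polylines
    vseg <- list()
    for (m in seq_len(nrow(st$geom$bundles))) {
      p <- st$geom$bundles$points[[m]]
      if (nrow(p) < 2) next
      for (s in seq_len(nrow(p) - 1)) {
        if (p[s, 1] == p[s + 1, 1] && p[s, 2] != p[s + 1, 2]) {
          vseg[[length(vseg) + 1L]] <- p[s, 1]
        }
      }
    }
    xs <- unlist(vseg)
    expect_equal(anyDuplicated(xs), 0)
  }
})

test_that("space parameters grow monotonically with the free space", {
  g <- gmsa_synth(n_guide_vertices = 8, n_comparative = 3, seed = 321)
  st1 <- full_stages(g, gmsa_space_params(fs = 4))
  st2 <- full_stages(g, gmsa_space_params(fs = 8))
  if (nrow(st1$routes$slots) > 0) {
    expect_gt(st2$routes$space$needed_inter_layer_space,
              st1$routes$space$needed_inter_layer_space)
  }
  # a gap with k slots needs at least k slot widths plus separations
  sl <- st1$routes$slots
  if (nrow(sl)) {
    kmax <- max(table(sl$gap))
    expect_gte(st1$routes$space$needed_inter_layer_space,
               kmax * (1 + 4) + 2 * 6)
  }
})

test_that("polylines are orthogonal with bounded bends", {
  for (k in 1:20) {
    g <- gmsa_synth(n_guide_vertices = sample(5:15, 1),
                    n_comparative = sample(1:5, 1), seed = 15000 + k)
    st <- full_stages(g)
    b <- st$geom$bundles
    for (m in seq_len(nrow(b))) {
      p <- b$points[[m]]
      seg_ok <- vapply(seq_len(nrow(p) - 1), function(s) {
        p[s, 1] == p[s + 1, 1] || p[s, 2] == p[s + 1, 2]
      }, logical(1))
      expect_true(all(seg_ok))
    }
    expect_true(all(b$bends[b$span == 1L] <= 2L))
    expect_true(all(b$bends[b$span > 1L] <= 4L))
  }
})

test_that("edge endpoints lie exactly on their vertex borders", {
  g <- gmsa_synth(n_guide_vertices = 10, n_comparative = 3, seed = 616)
  st <- full_stages(g)
  v <- st$geom$vertices
  vx <- stats::setNames(seq_len(nrow(v)), v$id)
  for (m in seq_len(nrow(st$geom$bundles))) {
    b <- st$geom$bundles[m, ]
    p <- b$points[[1]][c(1, nrow(b$points[[1]])), ]
    ru <- v[vx[[b$from]], ]; rv <- v[vx[[b$to]], ]
    expect_equal(p[1, 1], ru$x + ru$w)       # leaves u's right border
    expect_equal(p[2, 1], rv$x)              # enters v's left border
    expect_true(p[1, 2] >= ru$y && p[1, 2] <= ru$y + ru$h)
    expect_true(p[2, 2] >= rv$y && p[2, 2] <= rv$y + rv$h)
  }
})

test_that("no edge segment runs through a vertex rectangle interior", {
  for (k in 1:10) {
    g <- gmsa_synth(n_guide_vertices = sample(5:12, 1),
                    n_comparative = sample(1:4, 1), seed = 16000 + k)
    st <- full_stages(g)
    v <- st$geom$vertices
    eps <- 1e-6
    for (m in seq_len(nrow(st$geom$bundles))) {
      p <- st$geom$bundles$points[[m]]
      for (s in seq_len(nrow(p) - 1)) {
        x0 <- min(p[s, 1], p[s + 1, 1]); x1 <- max(p[s, 1], p[s + 1, 1])
        y0 <- min(p[s, 2], p[s + 1, 2]); y1 <- max(p[s, 2], p[s + 1, 2])
        hit <- v$x + eps < x1 & v$x + v$w - eps > x0 &
               v$y + eps < y1 & v$y + v$h - eps > y0
        expect_false(any(hit))
      }
    }
  }
})
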