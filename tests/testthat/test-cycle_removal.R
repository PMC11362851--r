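test_that("a guide-only graph becomes a simple forward chain", {
  g <- mk_graph(c("a", "b", "c"))
  dag <- gmsa_build_dag(g)
  expect_identical(dag$edges$from, c("a", "b"))
  expect_identical(dag$edges$to, c("b", "c"))
  eps_ab <- dag$epsilon[[gmsalayout:::edge_key("a", "b")]]
  expect_equal(eps_ab$direction, "forward")
  expect_equal(eps_ab$sequence, "gs")
})

test_that("bypath decomposition partitions the adjacencies of a sequence", {
  expect_identical(gmsa_decompose_bypaths(c("a", "b", "c"), c("a", "b", "c")),
                   list(c("a", "b"), c("b", "c")))
  expect_identical(gmsa_decompose_bypaths(c("a", "x", "y", "c"), c("a", "c")),
                   list(c("a", "x", "y", "c")))
  # oracle: scan splitting at processed vertices
  expect_identical(gmsa_decompose_bypaths(c("a", "x", "c", "y", "b"),
                                          c("a", "b", "c")),
                   list(c("a", "x", "c"), c("c", "y", "b")))
  expect_error(gmsa_decompose_bypaths(c("x", "a"), c("a")), "anchoring")
})

test_that("a back-running bypath is reversed with backward tuples", {
  # hand trace of the published reversal rule: bypath (c,x,a) has
  # a not-in sigma(c) and c in sigma(a), so it is added reversed
  g <- mk_graph(c("a", "b", "c"), c("c", "x", "a"))
  dag <- gmsa_build_dag(g)
  ek <- gmsalayout:::edge_key
  expect_setequal(paste(dag$edges$from, dag$edges$to),
                  c("a b", "b c", "a x", "x c"))
  expect_equal(dag$epsilon[[ek("a", "x")]]$direction, "backward")
  expect_equal(dag$epsilon[[ek("a", "x")]]$sequence, "cs1")
  expect_equal(dag$epsilon[[ek("x", "c")]]$direction, "backward")
  expect_true(dag$bypaths$reversed[dag$bypaths$id == 1L])
  expect_identical(gmsalayout:::dag_sources(dag), "a")
  expect_identical(gmsalayout:::dag_sinks(dag), "c")
})

test_that("an existing edge is reused and only gains a tuple", {
  g <- mk_graph(c("a", "b", "c"), c("a", "b", "c"))
  dag <- gmsa_build_dag(g)
  expect_equal(nrow(dag$edges), 2)
  eps <- dag$epsilon[[gmsalayout:::edge_key("a", "b")]]
  expect_equal(nrow(eps), 2)
  expect_setequal(eps$sequence, c("gs", "cs1"))
  expect_equal(unique(eps$direction), "forward")
})

test_that("the diamond case reverses the second bypath onto fresh vertices", {
  # after guide (a,b,c) and forward bypath (a,x,c), the bypath (c,y,a)
  # satisfies a not-in sigma(c), c in sigma(a): reversed to (a,y),(y,c)
  g <- mk_graph(c("a", "b", "c"), c("a", "x", "c"), c("c", "y", "a"))
  dag <- gmsa_build_dag(g)
  ek <- gmsalayout:::edge_key
  expect_false(dag$bypaths$reversed[2])
  expect_true(dag$bypaths$reversed[3])
  expect_equal(dag$epsilon[[ek("a", "x")]]$direction, "forward")
  expect_equal(dag$epsilon[[ek("a", "y")]]$direction, "backward")
  expect_equal(dag$epsilon[[ek("y", "c")]]$direction, "backward")
})

test_that("unrelated-endpoint bypaths follow the configured otherwise rule", {
  # comparative (a, p, b) with endpoints a, b where b not reachable from a
  # and a not reachable from b cannot arise off a guide chain, so build one
  # via two comparatives sharing only unreachable endpoints is not possible
  # either; instead check the flag on a case where both behaviors are legal
  g <- mk_graph(c("a", "b", "c", "d"), c("a", "p", "d"))
  d1 <- gmsa_build_dag(g, strict_otherwise_reverse = FALSE)
  d2 <- gmsa_build_dag(g, strict_otherwise_reverse = TRUE)
  # endpoints are related (d in sigma(a)), so both configs add forward
  expect_false(d1$bypaths$reversed[2])
  expect_identical(d1$edges, d2$edges)
})

test_that("incremental sigma/tau match from-scratch DFS after every bypath", {
  mismatches <- 0L
  for (k in 1:200) {
    g <- gmsa_synth(n_guide_vertices = sample(5:15, 1),
                    n_comparative = sample(0:3, 1), seed = 4000 + k)
    dag <- gmsa_build_dag(g, trace = TRUE)
    # at every snapshot, recompute reachability from scratch over the edges
    # inserted so far (DFS oracle) and compare with the incremental maps
    for (s in dag$trace) {
      sub <- dag$edges[seq_len(s$n_edges), ]
      reach <- oracle_reach(sub)
      redges <- sub; names(redges)[1:2] <- c("to", "from")
      back <- oracle_reach(redges)
      for (v in names(s$sigma)) {
        if (!setequal(s$sigma[[v]], reach[[v]] %||% character(0)) ||
            !setequal(s$tau[[v]], back[[v]] %||% character(0))) {
          mismatches <- mismatches + 1L
        }
      }
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("the DAG is acyclic by an independent igraph check", {
  skip_if_not_installed("igraph")
  for (k in 1:50) {
    g <- gmsa_synth(n_guide_vertices = sample(5:25, 1),
                    n_comparative = sample(0:5, 1), seed = 7000 + k)
    dag <- gmsa_build_dag(g)
    ig <- igraph::graph_from_data_frame(dag$edges[, c("from", "to")])
    expect_true(igraph::is_dag(ig))
  }
})

test_that("epsilon conserves every sequence adjacency exactly once", {
  for (k in 1:50) {
    g <- gmsa_synth(n_guide_vertices = sample(5:20, 1),
                    n_comparative = sample(0:5, 1), seed = 5000 + k)
    dag <- gmsa_build_dag(g)
    tuples <- dplyr::bind_rows(lapply(names(dag$epsilon), function(key) {
      e <- dag$epsilon[[key]]
      e$key <- key
      e
    }))
    expect_equal(nrow(tuples), gmsa_n_multiedges(g))
    # each (sequence, adjacency) appears exactly once: reconstruct the
    # adjacency from the key and the tuple direction and compare to input
    un <- gmsalayout:::edge_unkey(tuples$key)
    adj <- ifelse(tuples$direction == "forward",
                  paste(un$from, un$to), paste(un$to, un$from))
    got <- sort(paste(tuples$sequence, adj))
    want <- sort(unlist(lapply(seq_len(nrow(g$sequences)), function(s) {
      vs <- g$sequences$vertices[[s]]
      paste(g$sequences$name[s], utils::head(vs, -1), utils::tail(vs, -1))
    })))
    expect_identical(got, want)
  }
})

test_that("all edges of one bypath share one orientation", {
  for (k in 1:30) {
    g <- gmsa_synth(n_guide_vertices = sample(5:15, 1),
                    n_comparative = sample(1:4, 1), seed = 6000 + k)
    dag <- gmsa_build_dag(g)
    for (bp in seq_len(nrow(dag$bypaths))) {
      vs <- dag$bypaths$vertices[[bp]]
      if (dag$bypaths$reversed[bp]) vs <- rev(vs)
      # every adjacency of the oriented bypath points weakly forward in the
      # DAG: the reverse edge never exists for a pair the bypath created
      created <- dag$edges[dag$edges$bypath == dag$bypaths$id[bp], ]
      if (nrow(created) == 0) next
      pairs <- paste(utils::head(vs, -1), utils::tail(vs, -1))
      expect_true(all(paste(created$from, created$to) %in% pairs))
    }
  }
})
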