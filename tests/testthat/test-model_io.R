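test_that("validation accepts valid graphs and reports each violation kind", {
  g <- mk_graph(c("a", "b", "c"), c("a", "x", "c"))
  expect_equal(nrow(gmsa_validate(g)), 0)

  # revisiting a vertex breaks the path property
  g2 <- mk_graph(c("a", "b", "c"), c("a", "x", "c"), check = FALSE)
  g2$sequences$vertices[[2]] <- c("a", "x", "a")
  expect_true("path-distinct" %in% gmsa_validate(g2)$rule)

  # a comparative of length 1 violates the minimum path length
  g3 <- mk_graph(c("a", "b", "c"), c("a", "b"), check = FALSE)
  g3$sequences$vertices[[2]] <- "a"
  expect_true("path-length" %in% gmsa_validate(g3)$rule)

  # a comparative ending off the guide violates anchoring
  g4 <- mk_graph(c("a", "b", "c"), c("a", "x"), check = FALSE)
  expect_true("anchoring" %in% gmsa_validate(g4)$rule)
  expect_error(gmsa_graph(g4$blocks, g4$sequences), "anchoring")

  # one contig twice in an unmerged block breaks the single-hit rule
  g5 <- mk_graph(c("a", "b", "c"), check = FALSE)
  g5$blocks$rows[[1]] <- dplyr::bind_rows(g5$blocks$rows[[1]],
                                          g5$blocks$rows[[1]])
  expect_true("single-hit" %in% gmsa_validate(g5)$rule)

  # interval with i > j
  g6 <- mk_graph(c("a", "b", "c"), check = FALSE)
  g6$blocks$rows[[2]]$i <- g6$blocks$rows[[2]]$j + 10
  expect_true("interval-order" %in% gmsa_validate(g6)$rule)
})

test_that("JSON round trip is canonical and bit-identical", {
  g <- gmsa_synth(n_guide_vertices = 7, n_comparative = 2, seed = 11)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_gmsa(g, p1)
  g2 <- read_gmsa(p1)
  write_gmsa(g2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(g2$sequences$vertices, g$sequences$vertices)
  expect_identical(sort(g2$blocks$id), sort(g$blocks$id))
})

test_that("TSV export flattens one row per sequence interval", {
  g <- mk_graph(c("a", "b", "c"), c("a", "x", "c"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_gmsa(g, p, format = "tsv")
  flat <- utils::read.delim(p)
  expect_equal(nrow(flat), sum(purrr::map_int(g$blocks$rows, nrow)))
  expect_true(all(c("block_id", "genome", "contig", "i", "j", "sigma") %in%
                  names(flat)))
})

test_that("malformed JSON input names the problem", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", p)
  expect_error(read_gmsa(p), "malformed JSON")
  writeLines('{"foo": 1}', p)
  expect_error(read_gmsa(p), "blocks")
})

test_that("MAF ingestion sorts each contig's blocks by forward start", {
  maf <- system.file("extdata", "example_synthetic.maf",
                     package = "gmsalayout")
  g <- suppressWarnings(read_gmsa(maf, format = "maf"))
  # oracle: independent per-contig interval sort of the same file
  expect_identical(g$sequences$vertices[[1]], c("b1", "b2", "b3"))
  # G2.c2 originally ends on the lone block b4, which is trimmed off
  expect_identical(g$sequences$vertices[[2]], c("b1", "b2"))
  # G3.c3 is reverse complement: forward starts put its blocks in reverse
  expect_identical(g$sequences$vertices[[3]], c("b3", "b2", "b1"))
  # reverse-strand rows carry sigma = -1 with forward coordinates
  b1 <- g$blocks$rows[[match("b1", g$blocks$id)]]
  r3 <- b1[b1$genome == "G3", ]
  expect_equal(r3$sigma, -1)
  expect_equal(c(r3$i, r3$j), c(701, 800))
  expect_equal(nrow(gmsa_validate(g)), 0)
})

test_that("generator is deterministic and obeys its parameters", {
  a <- gmsa_synth(n_guide_vertices = 9, n_comparative = 3, seed = 5)
  b <- gmsa_synth(n_guide_vertices = 9, n_comparative = 3, seed = 5)
  expect_identical(a$sequences$vertices, b$sequences$vertices)
  expect_identical(a$blocks$id, b$blocks$id)

  g0 <- gmsa_synth(n_guide_vertices = 5, n_comparative = 0, seed = 2)
  expect_equal(nrow(g0$sequences), 1)
  expect_length(g0$sequences$vertices[[1]], 5)
  expect_equal(gmsa_n_multiedges(g0), 4)

  expect_error(gmsa_synth(n_guide_vertices = 1), "infeasible")
  expect_error(gmsa_synth(p_insertion = 1.5), "probabilities")
})

test_that("a certain inversion yields a reversed run that still validates", {
  g <- gmsa_synth(n_guide_vertices = 5, n_comparative = 1, p_insertion = 0,
                  p_deletion = 0, p_inversion = 1, seed = 8)
  cs <- g$sequences$vertices[[2]]
  gv <- g$sequences$vertices[[1]]
  expect_equal(nrow(gmsa_validate(g)), 0)
  # replay of the generator's rule: one interior run appears reversed
  pos <- match(cs, gv)
  expect_true(any(diff(pos) < 0))
  # reversed vertices are on the minus strand for the comparative contig
  rows2 <- gmsa_flat(g)
  neg <- rows2[rows2$genome == "G2" & rows2$sigma == -1, ]
  expect_gt(nrow(neg), 0)
})

test_that("1000 seeded parameter draws all produce valid graphs", {
  bad <- 0L
  for (k in seq_len(1000)) {
    set.seed(k)
    g <- gmsa_synth(n_guide_vertices = sample(2:12, 1),
                    n_comparative = sample(0:4, 1),
                    p_insertion = stats::runif(1, 0, 0.5),
                    p_deletion = stats::runif(1, 0, 0.5),
                    p_inversion = stats::runif(1, 0, 0.5),
                    max_insert_len = sample(1:4, 1), seed = k)
    if (nrow(gmsa_validate(g)) > 0) bad <- bad + 1L
    if (k %% 250 == 0 && bad > 0) break
  }
  expect_equal(bad, 0L)
})

test_that("derived multi-edge count equals the sum of adjacencies", {
  for (k in 1:25) {
    g <- gmsa_synth(n_guide_vertices = 5 + k %% 10, n_comparative = k %% 4,
                    seed = 100 + k)
    expect_equal(gmsa_n_multiedges(g),
                 sum(lengths(g$sequences$vertices) - 1L))
  }
})
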