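#' Generate a random, valid gMSA graph
#'
#' Seeded generator used for testing and demonstration.  It emulates the
#' block-order structure of a genome-wide alignment of closely related
#' genomes: a guide contig traversing `n_guide_vertices` alignment blocks in
#' order, and `n_comparative` comparative contigs derived from the guide by
#' three kinds of structural difference --
#' \itemize{
#'   \item *deletions*: each interior guide block is skipped with probability
#'     `p_deletion`;
#'   \item *insertions*: in each interior gap, with probability `p_insertion`
#'     a run of 1..`max_insert_len` new blocks private to that contig is
#'     inserted;
#'   \item *inversions*: with probability `p_inversion` one interior sub-run
#'     is reversed and its intervals flipped to the minus strand.
#' }
#' Endpoints are kept on the guide so the anchoring rule holds by
#' construction; the result always passes [gmsa_validate()].  The generator is
#' deterministic for a fixed seed and restores the caller's RNG state.
#'
#' @param n_guide_vertices Number of guide blocks (>= 2).
#' @param n_comparative Number of comparative sequences (>= 0).
#' @param p_insertion,p_deletion,p_inversion Event probabilities in \[0, 1\].
#' @param max_insert_len Maximum length of one inserted run (>= 1).
#' @param seed Integer RNG seed; recorded in the result as attribute `"seed"`.
#' @return A `gmsa_graph`.
#' @examples
#' g <- gmsa_synth(n_guide_vertices = 8, n_comparative = 2, seed = 42)
#' g
#' @export
gmsa_synth <- function(n_guide_vertices = 10, n_comparative = 2,
                       p_insertion = 0.15, p_deletion = 0.15,
                       p_inversion = 0.10, max_insert_len = 3, seed = 1) {
  if (n_guide_vertices < 2) {
    abort("infeasible parameters: need at least 2 guide vertices")
  }
  if (n_comparative < 0 || max_insert_len < 1) {
    abort("infeasible parameters: n_comparative >= 0, max_insert_len >= 1")
  }
  probs <- c(p_insertion, p_deletion, p_inversion)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  n <- as.integer(n_guide_vertices)
  gid <- sprintf("g%03d", seq_len(n))
  glen <- sample(100:2000, n, replace = TRUE)

  # block registry: id -> list(length, rows accumulated as data frames)
  blocks <- new.env(parent = emptyenv())
  add_row <- function(id, genome, contig, i, j, sigma) {
    b <- blocks[[id]]
    b$rows[[length(b$rows) + 1L]] <- list(genome = genome, contig = contig,
                                          i = i, j = j, sigma = sigma)
    blocks[[id]] <- b
  }
  pos <- 1
  for (k in seq_len(n)) {
    blocks[[gid[k]]] <- list(length = glen[k], rows = list())
    add_row(gid[k], "G1", "c1", pos, pos + glen[k] - 1, 1)
    pos <- pos + glen[k] + sample(0:50, 1)
  }

  sequences <- list(list(name = "gs", genome = "G1", contig = "c1",
                         vertices = gid))

  # size-safe sample: never triggers sample()'s scalar expansion
  pick <- function(x) x[sample.int(length(x), 1L)]

  for (cs in seq_len(n_comparative)) {
    genome <- paste0("G", cs + 1L)
    contig <- paste0("c", cs + 1L)
    vs <- gid
    # deletions: interior only, endpoints stay anchored on the guide
    if (n > 2) {
      drop <- stats::runif(n - 2) < p_deletion
      vs <- vs[c(TRUE, !drop, TRUE)]
    }
    strand <- stats::setNames(rep(1, length(vs)), vs)
    # insertions between consecutive retained blocks
    ins_counter <- 0L
    out <- vs[1]
    for (k in seq_len(length(vs) - 1L)) {
      if (stats::runif(1) < p_insertion) {
        m <- pick(seq_len(max_insert_len))
        new_ids <- sprintf("i%d_%03d", cs, ins_counter + seq_len(m))
        ins_counter <- ins_counter + m
        for (id in new_ids) {
          blocks[[id]] <- list(length = sample(100:2000, 1), rows = list())
          strand[id] <- 1
        }
        out <- c(out, new_ids)
      }
      out <- c(out, vs[k + 1L])
    }
    vs <- out
    # at most one inversion event over an interior sub-run
    if (length(vs) >= 4 && stats::runif(1) < p_inversion) {
      a <- pick(2:(length(vs) - 2L))
      b <- pick((a + 1L):(length(vs) - 1L))
      vs[a:b] <- rev(vs[a:b])
      strand[vs[a:b]] <- -1
    }
    # interval rows along the comparative contig
    pos <- 1
    for (id in vs) {
      len <- blocks[[id]]$length
      add_row(id, genome, contig, pos, pos + len - 1, strand[[id]])
      pos <- pos + len + sample(0:50, 1)
    }
    sequences[[length(sequences) + 1L]] <-
      list(name = paste0("cs", cs), genome = genome, contig = contig,
           vertices = vs)
  }

  ids <- ls(blocks, sorted = TRUE)
  block_tbl <- tibble(
    id = ids,
    length_nt = map_dbl(ids, function(id) blocks[[id]]$length),
    merged_from = map(ids, function(id) id),
    rows = map(ids, function(id) {
      r <- blocks[[id]]$rows
      fast_tbl(genome = map_chr(r, "genome"), contig = map_chr(r, "contig"),
               i = map_dbl(r, "i"), j = map_dbl(r, "j"),
               sigma = map_dbl(r, "sigma"))
    })
  )
  seq_tbl <- tibble(
    name = map_chr(sequences, "name"),
    genome = map_chr(sequences, "genome"),
    contig = map_chr(sequences, "contig"),
    color = gmsa_palette(length(sequences)),
    vertices = map(sequences, "vertices")
  )
  g <- gmsa_graph(block_tbl, seq_tbl, check = TRUE)
  attr(g, "seed") <- seed
  g
}
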