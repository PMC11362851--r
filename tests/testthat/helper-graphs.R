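# Build a small gMSA graph directly from vertex sequences (guide first).
# Interval rows are synthesised so that all model invariants hold.
mk_graph <- function(..., check = TRUE) {
  seqs <- list(...)
  ids <- unique(unlist(seqs))
  rows_env <- new.env(parent = emptyenv())
  for (s in seq_along(seqs)) {
    genome <- paste0("G", s)
    contig <- paste0("c", s)
    for (k in seq_along(seqs[[s]])) {
      id <- seqs[[s]][k]
      rows_env[[id]] <- rbind(rows_env[[id]],
                              data.frame(genome = genome, contig = contig,
                                         i = (k - 1) * 1000 + 1,
                                         j = (k - 1) * 1000 + 500,
                                         sigma = 1))
    }
  }
  blocks <- tibble::tibble(
    id = ids, length_nt = 500, merged_from = as.list(ids),
    rows = lapply(ids, function(id) tibble::as_tibble(rows_env[[id]]))
  )
  sequences <- tibble::tibble(
    name = c("gs", if (length(seqs) > 1) paste0("cs", seq_len(length(seqs) - 1L))),
    genome = paste0("G", seq_along(seqs)),
    contig = paste0("c", seq_along(seqs)),
    color = gmsalayout:::gmsa_palette(length(seqs)),
    vertices = seqs
  )
  gmsa_graph(blocks, sequences, check = check)
}

# independent reachability oracle: plain DFS over the current edge list
oracle_reach <- function(edges) {
  verts <- unique(c(edges$from, edges$to))
  adj <- split(edges$to, edges$from)
  res <- list()
  for (v in verts) {
    seen <- character(0)
    stack <- adj[[v]] %||% character(0)
    while (length(stack)) {
      w <- stack[1]; stack <- stack[-1]
      if (w %in% seen) next
      seen <- c(seen, w)
      stack <- c(stack, adj[[w]] %||% character(0))
    }
    res[[v]] <- sort(seen)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force crossing count from explicit per-layer vertex positions
oracle_crossings <- function(vorder, proper_edges) {
  pos <- stats::setNames(vorder$pos, vorder$vertex)
  total <- 0L
  for (gp in unique(proper_edges$gap)) {
    e <- proper_edges[proper_edges$gap == gp, ]
    n <- nrow(e)
    if (n < 2) next
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        d1 <- pos[[e$from[a]]] - pos[[e$from[b]]]
        d2 <- pos[[e$to[a]]] - pos[[e$to[b]]]
        if (d1 * d2 < 0) total <- total + 1L
      }
    }
  }
  total
}

# crossing count for an explicit block-set permutation (used by the
# exhaustive-optimum checks)
crossings_of_order <- function(bs, ord) {
  vo <- gmsa_vertex_order(bs, ord)
  oracle_crossings(vo, bs$edges)
}

# all permutations of a small integer vector
perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    for (p in perms(x[-k])) out[[length(out) + 1L]] <- c(x[k], p)
  }
  out
}

# standard synthetic sweep used by several suites
synth_sweep <- function(n, seed_base = 1000, guide_range = c(5, 60),
                        comp_range = c(0, 8)) {
  lapply(seq_len(n), function(k) {
    set.seed(seed_base + k)
    gmsa_synth(
      n_guide_vertices = sample(guide_range[1]:guide_range[2], 1),
      n_comparative = sample(comp_range[1]:comp_range[2], 1),
      seed = seed_base + k
    )
  })
}
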