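# key for a directed DAG edge;  never occurs in block ids we accept
edge_key <- function(u, v) paste(u, v, sep = "")
edge_unkey <- function(k) {
  parts <- strsplit(k, "", fixed = TRUE)
  list(from = map_chr(parts, 1), to = map_chr(parts, 2))
}

# Integer-indexed cycle-removal state.  Reachability is one logical matrix
# `reach` with reach[u, v] = TRUE iff a path u -> v exists over the inserted
# edges: sigma(v) is its row, tau(v) its column, so the symmetric predecessor
# update falls out of the same matrix.
new_dag_state <- function(vids) {
  st <- new.env(parent = emptyenv())
  n <- length(vids)
  st$vids <- vids
  st$idx <- stats::setNames(seq_len(n), vids)
  st$reach <- matrix(FALSE, n, n)
  st$emat <- matrix(0L, n, n)                 # edge index, 0 = absent
  st$processed <- logical(n)
  st$order <- integer(0)                      # processing order (indices)
  st$e_from <- integer(0); st$e_to <- integer(0)
  st$e_creator <- character(0); st$e_bypath <- integer(0)
  st$t_edge <- integer(0)                     # tuple -> edge index
  st$t_dir <- character(0); st$t_seq <- character(0)
  st
}

st_process <- function(st, v) {
  if (!st$processed[v]) {
    st$processed[v] <- TRUE
    st$order <- c(st$order, v)
  }
}

# insert DAG edge (u, v) and close reachability: sigma_u gains {v} U sigma_v,
# then every predecessor of u gains sigma_u (the published two-step update;
# the tau side is the same matrix read by column)
st_add_edge <- function(st, u, v, creator, bypath) {
  m <- length(st$e_from) + 1L
  st$e_from[m] <- u; st$e_to[m] <- v
  st$e_creator[m] <- creator; st$e_bypath[m] <- bypath
  st$emat[u, v] <- m
  st$reach[u, ] <- st$reach[u, ] | st$reach[v, ]
  st$reach[u, v] <- TRUE
  W <- which(st$reach[, u])
  if (length(W)) {
    st$reach[W, ] <- st$reach[W, , drop = FALSE] |
      matrix(st$reach[u, ], length(W), ncol(st$reach), byrow = TRUE)
  }
  m
}

st_add_tuple <- function(st, edge_idx, direction, sequence) {
  k <- length(st$t_edge) + 1L
  st$t_edge[k] <- edge_idx
  st$t_dir[k] <- direction
  st$t_seq[k] <- sequence
}

# add one oriented path (guide or bypath); `path` holds vertex indices in DAG
# direction, `reversed` says whether that reverses the original sequence
st_add_path <- function(st, path, seqname, reversed, bypath) {
  for (k in seq_len(length(path) - 1L)) {
    u <- path[k]; v <- path[k + 1L]
    st_process(st, u); st_process(st, v)
    if (st$emat[u, v] > 0L) {
      # DAG edge (u,v) exists; original adjacency is (u,v) unless reversed
      st_add_tuple(st, st$emat[u, v],
                   if (reversed) "backward" else "forward", seqname)
    } else if (st$emat[v, u] > 0L) {
      # only the opposite DAG edge exists: the tuple lands there
      st_add_tuple(st, st$emat[v, u],
                   if (reversed) "forward" else "backward", seqname)
    } else {
      m <- st_add_edge(st, u, v, creator = seqname, bypath = bypath)
      st_add_tuple(st, m, if (reversed) "backward" else "forward", seqname)
    }
  }
}

#' Split a vertex sequence into bypaths
#'
#' A bypath is a sub-path whose first and last vertices are already processed
#' and whose interior vertices are not.  The bypaths partition the
#' adjacencies of the sequence: concatenating them (dropping repeated
#' junction vertices) reproduces the sequence.
#'
#' @param s Character vector of vertex ids (one vertex sequence).
#' @param processed Character vector of already processed vertex ids.
#' @return A list of character vectors, each a bypath.
#' @export
gmsa_decompose_bypaths <- function(s, processed) {
  n <- length(s)
  if (n < 2L) abort("vertex sequence shorter than 2")
  anchors <- which(s %in% processed)
  if (length(anchors) == 0 || anchors[1] != 1L || anchors[length(anchors)] != n) {
    abort("anchoring violated: sequence must start and end at processed vertices")
  }
  lapply(seq_len(length(anchors) - 1L), function(k) {
    s[anchors[k]:anchors[k + 1L]]
  })
}

#' Transform a gMSA graph into a single-source, single-sink DAG
#'
#' Cycle removal for the layered layout.  The guide sequence is processed
#' first with all its edges in original direction; each comparative sequence
#' is then split into bypaths at the already processed vertices and each
#' bypath is inserted whole, either forward or reversed:
#' \itemize{
#'   \item if the bypath's last vertex is already a successor of its first
#'     (`vn` in `sigma(v0)`), it is added forward;
#'   \item if the first is a successor of the last (`v0` in `sigma(vn)`),
#'     adding it forward would close a cycle, so the whole bypath is reversed;
#'   \item if the endpoints are unrelated, the default keeps the original
#'     reading direction (forward); `strict_otherwise_reverse = TRUE` reverses
#'     in this case too.
#' }
#' Between two vertices at most one DAG edge ever exists; the multiple-edge
#' map `epsilon` records, per DAG edge, one `(direction, sequence)` tuple for
#' every original adjacency it carries, so the drawing can restore original
#' directions later.  Successor/predecessor reachability (`sigma`/`tau`) is
#' maintained incrementally while edges are inserted.
#'
#' The result has the guide's first vertex as its only source and the guide's
#' last vertex as its only sink.
#'
#' @param g A validated `gmsa_graph` (run [gmsa_validate()] first or let this
#'   abort on violations).
#' @param strict_otherwise_reverse Reverse bypaths whose endpoints are
#'   mutually unreachable (default `FALSE`: add them forward).
#' @param trace Record a snapshot of `sigma`, `tau` and the edge count after
#'   the guide and after every bypath insertion (for diagnostics and
#'   verification; default `FALSE`).
#' @return An object of class `gmsa_dag` with elements `vertices` (processing
#'   order), `edges` (tibble `from`, `to`, `creator`, `bypath`), `sigma`,
#'   `tau` (named lists of reachability sets), `epsilon` (named list keyed by
#'   edge, each a tibble `direction`, `sequence`) and `bypaths` (tibble `id`,
#'   `sequence`, `reversed`, `vertices`).
#' @export
gmsa_build_dag <- function(g, strict_otherwise_reverse = FALSE, trace = FALSE) {
  viol <- gmsa_validate(g)
  if (nrow(viol) > 0) {
    abort(c("cannot build DAG from invalid graph:",
            stats::setNames(paste(viol$rule, "--", viol$detail),
                            rep("x", nrow(viol)))))
  }
  vids <- unique(unlist(g$sequences$vertices))
  st <- new_dag_state(vids)
  gname <- g$sequences$name[1]
  reach_lists <- function() {
    processed <- st$vids[st$order]
    sig <- lapply(st$order, function(v) st$vids[st$reach[v, ]])
    tau <- lapply(st$order, function(v) st$vids[st$reach[, v]])
    list(sigma = stats::setNames(sig, processed),
         tau = stats::setNames(tau, processed))
  }
  snapshots <- list()
  snap <- function(id) {
    if (trace) {
      rl <- reach_lists()
      snapshots[[length(snapshots) + 1L]] <<-
        list(bypath = id, sigma = rl$sigma, tau = rl$tau,
             n_edges = length(st$e_from))
    }
  }
  st_add_path(st, unname(st$idx[guide_vertices(g)]), gname,
              reversed = FALSE, bypath = 0L)
  snap(0L)

  bypaths <- list(list(id = 0L, sequence = gname, reversed = FALSE,
                       vertices = guide_vertices(g)))
  bp_id <- 0L
  for (k in seq_len(nrow(g$sequences))[-1]) {
    sname <- g$sequences$name[k]
    bps <- gmsa_decompose_bypaths(g$sequences$vertices[[k]],
                                  st$vids[st$order])
    for (bp in bps) {
      bp_id <- bp_id + 1L
      pi <- unname(st$idx[bp])
      v0 <- pi[1]; vn <- pi[length(pi)]
      reversed <-
        if (st$reach[v0, vn]) FALSE
        else if (st$reach[vn, v0]) TRUE
        else strict_otherwise_reverse
      st_add_path(st, if (reversed) rev(pi) else pi, sname, reversed, bp_id)
      snap(bp_id)
      bypaths[[length(bypaths) + 1L]] <-
        list(id = bp_id, sequence = sname, reversed = reversed, vertices = bp)
    }
  }

  edges <- tibble(
    from = st$vids[st$e_from], to = st$vids[st$e_to],
    creator = st$e_creator, bypath = st$e_bypath
  )
  if (!is_acyclic(st$vids[st$order], edges)) {
    abort("internal consistency failure: cycle removal produced a cycle")
  }
  ekeys <- edge_key(edges$from, edges$to)
  eps <- lapply(split(seq_along(st$t_edge), st$t_edge), function(ti) {
    fast_tbl(direction = st$t_dir[ti], sequence = st$t_seq[ti])
  })
  names(eps) <- ekeys[as.integer(names(eps))]
  rl <- reach_lists()
  structure(list(
    vertices = unname(st$vids[st$order]),
    trace = if (trace) snapshots,
    edges = edges,
    sigma = rl$sigma,
    tau = rl$tau,
    epsilon = eps,
    bypaths = tibble(id = map_int(bypaths, "id"),
                     sequence = map_chr(bypaths, "sequence"),
                     reversed = map_lgl(bypaths, "reversed"),
                     vertices = map(bypaths, "vertices"))
  ), class = "gmsa_dag")
}

#' @export
print.gmsa_dag <- function(x, ...) {
  cat(sprintf("<gmsa_dag> %d vertices, %d edges, %d bypaths (%d reversed), %d tuples\n",
              length(x$vertices), nrow(x$edges), nrow(x$bypaths) - 1L,
              sum(x$bypaths$reversed), sum(map_int(x$epsilon, nrow))))
  invisible(x)
}

# Kahn topological check
is_acyclic <- function(vertices, edges) {
  if (nrow(edges) == 0) return(TRUE)
  indeg <- stats::setNames(rep(0L, length(vertices)), vertices)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  out <- split(edges$to, edges$from)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    seen <- seen + 1L
    for (w in out[[v]] %||% character()) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen == length(vertices)
}

# sources/sinks of a gmsa_dag
dag_sources <- function(dag) setdiff(dag$vertices, dag$edges$to)
dag_sinks <- function(dag) setdiff(dag$vertices, dag$edges$from)

#' Export a layout DAG as Graphviz DOT (debug aid)
#'
#' Edges are annotated with their multiple-edge tuples.
#' @param dag A `gmsa_dag`.
#' @return A character scalar with the DOT source.
#' @export
gmsa_dag_dot <- function(dag) {
  lab <- map_chr(seq_len(nrow(dag$edges)), function(k) {
    e <- dag$epsilon[[edge_key(dag$edges$from[k], dag$edges$to[k])]]
    paste(sprintf("%s:%s", substr(e$direction, 1, 1), e$sequence),
          collapse = ",")
  })
  paste0("digraph gmsa {\n  rankdir=LR;\n",
         paste(sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                       dag$edges$from, dag$edges$to, lab), collapse = "\n"),
         "\n}\n")
}
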