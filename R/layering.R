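topological_order <- function(vertices, edges) {
  indeg <- stats::setNames(rep(0L, length(vertices)), vertices)
  if (nrow(edges)) {
    tab <- table(edges$to)
    indeg[names(tab)] <- as.integer(tab)
  }
  out <- if (nrow(edges)) split(edges$to, edges$from) else list()
  queue <- vertices[indeg[vertices] == 0L]
  ord <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (w in out[[v]] %||% character()) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) != length(vertices)) abort("graph is not acyclic")
  ord
}

#' Assign layers by the longest-path algorithm
#'
#' Every vertex is placed on the layer equal to the length of the longest
#' path from the DAG's single source to it; layers are 0-based and become the
#' horizontal position (columns, left to right) of the drawing.  Because the
#' guide runs source-to-sink and every inserted bypath only pushes downstream
#' vertices further right, guide vertices occupy strictly increasing layers,
#' with the guide's first vertex on layer 0 and its last on the maximum
#' layer.
#'
#' @param dag A `gmsa_dag` from [gmsa_build_dag()].
#' @return Named integer vector: vertex id -> layer.
#' @export
gmsa_assign_layers <- function(dag) {
  ord <- topological_order(dag$vertices, dag$edges)
  layer <- stats::setNames(rep(0L, length(ord)), ord)
  if (nrow(dag$edges)) {
    incoming <- split(seq_len(nrow(dag$edges)), dag$edges$to)
    for (v in ord) {
      idx <- incoming[[v]]
      if (length(idx)) {
        layer[v] <- max(layer[dag$edges$from[idx]]) + 1L
      }
    }
  }
  layer
}

#' Make a layering proper by inserting dummy vertices
#'
#' An edge spanning `s > 1` layers (a *long edge*) is replaced by a chain of
#' `s - 1` dummy vertices connected by `s` tight dummy edges, one per
#' traversed layer.  Every dummy edge of a chain inherits the full
#' multiple-edge tuple set of the long edge it replaces; the long edge itself
#' is removed from the edge set and from `epsilon`.
#'
#' @param dag A `gmsa_dag`.
#' @param layer Named layer vector from [gmsa_assign_layers()].
#' @return An object of class `gmsa_proper`: `layer` (incl. dummies), `edges`
#'   (tibble `from`, `to`, `gap`, `origin`, `inner`), `dummies`, `chains`
#'   (named list: original long-edge key -> dummy chain), `epsilon` (keyed by
#'   proper edge), plus the originating `dag`.
#' @export
gmsa_make_proper <- function(dag, layer) {
  e_from <- character(0); e_to <- character(0); e_gap <- integer(0)
  e_origin <- character(0); e_inner <- logical(0)
  chains <- list()
  eps <- list()
  dummies <- character(0)
  for (k in seq_len(nrow(dag$edges))) {
    u <- dag$edges$from[k]; v <- dag$edges$to[k]
    key <- edge_key(u, v)
    span <- as.integer(layer[[v]] - layer[[u]])
    if (span < 1L) abort("layering violates edge direction")  # unreachable
    tuples <- dag$epsilon[[key]]
    if (span == 1L) {
      e_from <- c(e_from, u); e_to <- c(e_to, v)
      e_gap <- c(e_gap, layer[[u]]); e_origin <- c(e_origin, key)
      e_inner <- c(e_inner, FALSE)
      eps[[key]] <- tuples
    } else {
      ch <- sprintf("d:%s:%d", key, seq_len(span - 1L))
      layer[ch] <- layer[[u]] + seq_len(span - 1L)
      dummies <- c(dummies, ch)
      chains[[key]] <- ch
      nodes <- c(u, ch, v)
      m <- seq_len(span)
      e_from <- c(e_from, nodes[m]); e_to <- c(e_to, nodes[m + 1L])
      e_gap <- c(e_gap, layer[[u]] + m - 1L)
      e_origin <- c(e_origin, rep(key, span))
      e_inner <- c(e_inner, m > 1L & m < span)
      for (mm in m) eps[[edge_key(nodes[mm], nodes[mm + 1L])]] <- tuples
    }
  }
  structure(list(
    layer = layer,
    edges = tibble(from = e_from, to = e_to, gap = e_gap,
                   origin = e_origin, inner = e_inner),
    dummies = dummies,
    chains = chains,
    epsilon = eps,
    dag = dag
  ), class = "gmsa_proper")
}

#' @export
print.gmsa_proper <- function(x, ...) {
  cat(sprintf("<gmsa_proper> %d layers, %d vertices (%d dummies), %d tight edges\n",
              max(x$layer) + 1L, length(x$layer), length(x$dummies),
              nrow(x$edges)))
  invisible(x)
}
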