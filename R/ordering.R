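#' Partition a properly layered DAG into blocks and block-sets
#'
#' A *block* is a single real vertex or a maximal chain of adjacent dummy
#' vertices (one long edge's chain).  A *block-set* is the ordered run of
#' blocks induced by one bypath: its interior vertices plus the dummy chains
#' of the long edges it created, sorted from lowest to highest layer.  The
#' guide sequence forms one block-set of its own.  Bypaths that contributed
#' no block (length-2 bypaths whose edge stayed tight, or whose edge was
#' already present) induce no block-set.  Every real and dummy vertex belongs
#' to exactly one block of exactly one block-set; block-sets are the unit of
#' crossing reduction and of vertical positioning.
#'
#' @param proper A `gmsa_proper` from [gmsa_make_proper()].
#' @return An object of class `gmsa_blocksets`: `sets` (tibble `set_id`,
#'   `origin`, `sequence`, `guide`, `layer_min`, `layer_max`, `blocks` = list
#'   of member-vertex vectors), `vertex_set` (named vertex -> set_id),
#'   `edges` (tibble of proper edges annotated with endpoint set ids), and
#'   the `proper` object.
#' @export
gmsa_block_sets <- function(proper) {
  dag <- proper$dag
  owner <- new.env(parent = emptyenv())   # vertex/chain owner -> bypath id
  for (k in seq_len(nrow(dag$bypaths))) {
    id <- dag$bypaths$id[k]
    vs <- dag$bypaths$vertices[[k]]
    own <- if (id == 0L) vs else vs[-c(1L, length(vs))]
    for (v in own) owner[[v]] <- id
  }
  edge_owner <- stats::setNames(dag$edges$bypath,
                                edge_key(dag$edges$from, dag$edges$to))

  # blocks per owner: real vertices and dummy chains, keyed by min layer
  per_owner <- list()
  add_block <- function(own, members) {
    key <- as.character(own)
    per_owner[[key]] <<- c(per_owner[[key]], list(members))
  }
  for (v in dag$vertices) {
    if (is.null(owner[[v]])) {
      abort(paste0("internal failure: vertex `", v, "` not covered by a bypath"))
    }
    add_block(owner[[v]], v)
  }
  for (key in names(proper$chains)) {
    add_block(edge_owner[[key]], proper$chains[[key]])
  }

  bp_ids <- sort(as.integer(names(per_owner)))
  seq_of <- stats::setNames(dag$bypaths$sequence, as.character(dag$bypaths$id))
  ordered_blocks <- lapply(bp_ids, function(own) {
    blocks <- per_owner[[as.character(own)]]
    lmin <- map_int(blocks, function(b) min(proper$layer[b]))
    blocks[order(lmin)]
  })
  sets <- fast_tbl(
    set_id = seq_along(bp_ids), origin = bp_ids,
    sequence = unname(seq_of[as.character(bp_ids)]),
    guide = bp_ids == 0L,
    layer_min = map_int(ordered_blocks,
                        function(bl) min(map_int(bl, function(b) min(proper$layer[b])))),
    layer_max = map_int(ordered_blocks,
                        function(bl) max(map_int(bl, function(b) max(proper$layer[b])))),
    blocks = ordered_blocks
  )

  vertex_set <- integer(0)
  for (s in seq_len(nrow(sets))) {
    mem <- unlist(sets$blocks[[s]])
    vertex_set[mem] <- sets$set_id[s]
  }
  if (length(vertex_set) != length(proper$layer) ||
      anyNA(vertex_set[names(proper$layer)])) {
    abort("internal failure: block-sets do not cover every vertex exactly once")
  }
  edges <- proper$edges
  edges$sf <- vertex_set[edges$from]
  edges$st <- vertex_set[edges$to]
  # plain-vector views and a gap index for the crossing machinery
  e <- list(gap = edges$gap, sf = unname(edges$sf), st = unname(edges$st),
            inner = edges$inner)
  gap_index <- split(seq_along(e$gap), e$gap)
  structure(list(sets = sets, vertex_set = vertex_set, edges = edges,
                 e = e, gap_index = gap_index, proper = proper),
            class = "gmsa_blocksets")
}

#' @export
print.gmsa_blocksets <- function(x, ...) {
  cat(sprintf("<gmsa_blocksets> %d block-sets, %d blocks over %d layers\n",
              nrow(x$sets), sum(lengths(x$sets$blocks)),
              max(x$proper$layer) + 1L))
  invisible(x)
}

# initial vertical order of the block-sets: guide first, then bypaths in
# processing (creation) order -- deterministic
initial_set_order <- function(bs) bs$sets$set_id[order(bs$sets$origin)]

eta_from_order <- function(ord) {
  eta <- integer(max(ord))
  eta[ord] <- seq_along(ord) - 1L
  eta
}

#' Derive the per-layer vertex order from block-set positions
#'
#' Within one layer every block-set occupies at most one block (bypath layers
#' strictly increase), so the vertical order of the vertices in a layer is
#' exactly the eta-order of their block-sets.
#'
#' @param bs A `gmsa_blocksets`.
#' @param order Integer vector of set ids, top to bottom; defaults to the
#'   initial order.
#' @return Tibble `vertex`, `layer`, `pos` (0-based position within layer).
#' @export
gmsa_vertex_order <- function(bs, order = initial_set_order(bs)) {
  eta <- eta_from_order(order)
  vs <- names(bs$vertex_set)
  tib <- tibble(vertex = vs,
                layer = as.integer(bs$proper$layer[vs]),
                eta = eta[bs$vertex_set[vs]])
  tib <- tib[order(tib$layer, tib$eta), ]
  tib$pos <- stats::ave(seq_len(nrow(tib)), tib$layer,
                        FUN = function(x) seq_along(x) - 1L)
  tib$eta <- NULL
  tib
}

#' Count edge crossings of a block-set order
#'
#' Exact pairwise count over every adjacent-layer gap: two edges of one gap
#' cross iff their endpoint orders differ between the left and the right
#' layer.  Since per layer each block-set holds at most one vertex, endpoint
#' order is the eta-order of the endpoint block-sets; edges sharing an
#' endpoint never cross.  With `by_type = TRUE` the count is split by the
#' number of inner (dummy-chain) edges involved: Type 0 (two outer), Type 1
#' (one inner), Type 2 (two inner; never produced by this layout because a
#' dummy chain lies inside a single block at a single position).
#'
#' @param bs A `gmsa_blocksets`.
#' @param order Integer vector of set ids (top to bottom).
#' @param by_type Return a named vector `c(type0, type1, type2)` instead of a
#'   total.
#' @return Crossing count (or per-type counts).
#' @export
gmsa_count_crossings <- function(bs, order = initial_set_order(bs),
                                 by_type = FALSE) {
  eta <- eta_from_order(order)
  e <- bs$e
  total <- c(type0 = 0L, type1 = 0L, type2 = 0L)
  for (idx in bs$gap_index) {
    if (length(idx) < 2L) next
    l <- eta[e$sf[idx]]; r <- eta[e$st[idx]]; inn <- e$inner[idx]
    dl <- outer(l, l, "-"); dr <- outer(r, r, "-")
    cross <- dl * dr < 0 & upper.tri(dl)
    if (!any(cross)) next
    if (by_type) {
      ti <- outer(inn, inn, "+")[cross]
      total <- total + c(sum(ti == 0), sum(ti == 1), sum(ti == 2))
    } else {
      total[1] <- total[1] + sum(cross)
    }
  }
  if (by_type) total else as.integer(sum(total))
}

# crossings involving set X as a function of X's insertion slot p = 0..n-1.
# others_pos: 0-based positions of the other sets once X is removed; X at
# slot p precedes exactly the sets with others_pos >= p.
crossings_varying <- function(bs, x, others_pos, n) {
  e <- bs$e
  xi <- which(e$sf == x | e$st == x)
  if (length(xi) == 0L) return(rep(0L, n))
  p <- seq_len(n) - 1L
  out <- rep(0L, n)
  cmp_side <- function(a, b) {
    # order indicator vector over p for one side of an edge pair
    if (a == b) return(NULL)                    # same set: shared vertex
    if (a == x) return(p <= others_pos[b])
    if (b == x) return(others_pos[a] < p)
    rep(others_pos[a] < others_pos[b], n)
  }
  for (ei in xi) {
    cand <- bs$gap_index[[as.character(e$gap[ei])]]
    for (fi in cand) {
      if (fi == ei) next
      both_x <- (e$sf[fi] == x || e$st[fi] == x)
      if (both_x && fi < ei) next   # count x-x pairs once
      c1 <- cmp_side(e$sf[ei], e$sf[fi])
      c2 <- cmp_side(e$st[ei], e$st[fi])
      if (is.null(c1) || is.null(c2)) next
      out <- out + (c1 != c2)
    }
  }
  out
}

#' Crossing reduction by global sifting of block-sets
#'
#' The adapted global sifting heuristic: instead of single blocks, whole
#' block-sets are moved through every vertical position and kept at the
#' position with the fewest crossings (ties broken toward the topmost
#' position).  Shifting a block-set never changes the relative order of the
#' remaining sets, so only crossings of edge pairs touching the shifted set
#' have to be re-evaluated per candidate position.  Sifting every block-set
#' once is one round; rounds stop early when a full round moves nothing or
#' leaves the crossing count unchanged.
#' The guide block-set takes part like any other set.  Because each dummy
#' chain lies inside one block at one position, Type 2 (inner-inner)
#' crossings cannot occur.
#'
#' @param bs A `gmsa_blocksets`.
#' @param rounds Maximum number of sifting rounds (default 10).
#' @param order Starting order; defaults to guide first, then bypaths in
#'   creation order.
#' @return A list: `order` (set ids top to bottom), `index_gs` (position of
#'   the guide block-set, 1-based), `crossings` (integer vector: initial
#'   count followed by the count after each executed round), `rounds_run`.
#' @export
gmsa_global_sift <- function(bs, rounds = 10, order = initial_set_order(bs)) {
  n <- length(order)
  current <- gmsa_count_crossings(bs, order)
  history <- current
  if (n > 1L && rounds > 0) {
    for (r in seq_len(rounds)) {
      changed <- FALSE
      for (x in bs$sets$set_id) {
        old_slot <- match(x, order) - 1L   # re-inserting here restores order
        others <- order[order != x]
        others_pos <- integer(max(c(others, 1L)))
        others_pos[others] <- seq_along(others) - 1L
        varying <- crossings_varying(bs, x, others_pos, n)
        # crossings not involving X are invariant under X's position, so the
        # running total splits into rest + varying(p)
        totals <- (current - varying[old_slot + 1L]) + varying
        p_star <- which.min(totals) - 1L   # ties: topmost wins
        current <- totals[p_star + 1L]
        order <- append(others, x, after = p_star)
        if (p_star != old_slot) changed <- TRUE
      }
      history <- c(history, current)
      # stop when a full round neither moved a set nor reduced crossings
      if (!changed || current == 0L ||
          current == history[length(history) - 1L]) break
    }
  }
  list(order = order, index_gs = match(bs$sets$set_id[bs$sets$guide], order),
       crossings = as.integer(history), rounds_run = length(history) - 1L)
}
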