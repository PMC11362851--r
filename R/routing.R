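#' Spacing and sizing parameters for edge routing and drawing
#'
#' All values are pixels.  `fs` is the free space inserted between two
#' adjacent edges ("FS"), `bs_border` the border space between a vertex
#' border or gap border and the nearest edge line ("BS").  A bundled edge is
#' drawn `member_px` per bundled sequence wide, capped at `width_cap`.  The
#' remaining values bound vertex size and spacing in the final drawing.
#'
#' @param fs Free space between adjacent edges.
#' @param bs_border Border space between vertex/gap border and an edge.
#' @param member_px Line width contributed by one bundled sequence.
#' @param width_cap Maximum bundle line width.
#' @param min_vertex_height Minimum uniform vertex height.
#' @param vertex_gap_y Vertical free space between adjacent tracks.
#' @param min_vertex_width,max_vertex_width Bounds for the block-length
#'   dependent vertex width.
#' @param min_inter_layer Minimum horizontal space between two layers.
#' @param margin Canvas margin.
#' @return A list of class `gmsa_space_params`.
#' @export
gmsa_space_params <- function(fs = 4, bs_border = 6, member_px = 1,
                              width_cap = 6, min_vertex_height = 18,
                              vertex_gap_y = 14, min_vertex_width = 30,
                              max_vertex_width = 90, min_inter_layer = 24,
                              margin = 20) {
  p <- list(fs = fs, bs_border = bs_border, member_px = member_px,
            width_cap = width_cap, min_vertex_height = min_vertex_height,
            vertex_gap_y = vertex_gap_y, min_vertex_width = min_vertex_width,
            max_vertex_width = max_vertex_width,
            min_inter_layer = min_inter_layer, margin = margin)
  if (any(unlist(p) <= 0)) abort("all space parameters must be > 0")
  structure(p, class = "gmsa_space_params")
}

#' Collapse dummy chains into drawable long-edge routes
#'
#' Reversing the reversed edges back is unnecessary -- the multiple-edge map
#' already records every original adjacency with its direction -- so the
#' preparation for drawing only replaces each dummy chain by one drawable
#' edge between its real endpoints.  The drawable edge carries the chain's
#' (uniform) tuple set and remembers the track its dummy block was stacked
#' on, which becomes the elevation of the long edge's horizontal run.  Tight
#' edges pass through unchanged.
#'
#' @param bs A `gmsa_blocksets`.
#' @param tracks Result of [gmsa_assign_tracks()].
#' @return Tibble of drawable edges: `key`, `from`, `to`, `span`,
#'   `gap_first`, `gap_last`, `route_track` (NA for tight edges), `tuples`
#'   (list of tibbles `direction`, `sequence`).
#' @export
gmsa_collapse_dummies <- function(bs, tracks) {
  proper <- bs$proper
  dag <- proper$dag
  layer <- proper$layer
  from <- dag$edges$from; to <- dag$edges$to
  key <- edge_key(from, to)
  span <- as.integer(layer[to] - layer[from])
  rt <- rep(NA_integer_, length(key))
  for (k in which(span > 1L)) {
    chain <- proper$chains[[key[k]]]
    nodes <- c(from[k], chain, to[k])
    e0 <- proper$epsilon[[edge_key(nodes[1], nodes[2])]]
    for (m in seq_len(span[k])) {
      if (!identical(proper$epsilon[[edge_key(nodes[m], nodes[m + 1L])]], e0)) {
        abort("internal failure: non-uniform epsilon along a dummy chain")
      }
    }
    rt[k] <- tracks$y[[chain[1]]]
  }
  tibble(key = key, from = from, to = to, span = span,
         gap_first = as.integer(layer[from]),
         gap_last = as.integer(layer[to]) - 1L,
         route_track = rt,
         tuples = unname(dag$epsilon[key]))
}

#' Bundle the multi-edges of the drawable edges
#'
#' Original edges sharing start vertex, end vertex and direction are bundled
#' into one drawn line whose width encodes the number of bundled sequences,
#' so each drawable edge yields at most two bundles (forward and/or
#' backward).
#'
#' @param drawable Tibble from [gmsa_collapse_dummies()].
#' @param params A `gmsa_space_params` (for the width cap).
#' @return Tibble of bundles: `bundle_id`, `key`, `from`, `to`, `span`,
#'   `gap_first`, `gap_last`, `route_track`, `direction`, `members` (list of
#'   sequence names), `n_members`, `width`.
#' @export
gmsa_bundle_edges <- function(drawable, params = gmsa_space_params()) {
  per <- lapply(seq_len(nrow(drawable)), function(k) {
    tup <- drawable$tuples[[k]]
    dirs <- intersect(c("forward", "backward"), unique(tup$direction))
    list(k = rep(k, length(dirs)), dirs = dirs,
         members = lapply(dirs, function(d) tup$sequence[tup$direction == d]))
  })
  ks <- unlist(lapply(per, `[[`, "k"))
  dirs <- unlist(lapply(per, `[[`, "dirs"))
  members <- unlist(lapply(per, `[[`, "members"), recursive = FALSE)
  tibble(bundle_id = paste0(drawable$key[ks], "#", dirs),
         key = drawable$key[ks], from = drawable$from[ks],
         to = drawable$to[ks], span = drawable$span[ks],
         gap_first = drawable$gap_first[ks],
         gap_last = drawable$gap_last[ks],
         route_track = drawable$route_track[ks],
         direction = dirs, members = members,
         n_members = lengths(members),
         width = pmin(lengths(members) * params$member_px, params$width_cap))
}

# connection-point placement: one row per bundle endpoint with its zone and
# its distance bookkeeping.  `dist` is measured from the top border (up
# zone), from the bottom border (down zone), or from the vertex center
# (straight zone, signed).  Ranks in the up/down zones are allocated per
# (gap, track, zone) shared across the two facing borders -- the left
# vertex's edges first, so their space is blocked at the right vertex.
route_connections <- function(bundles, tracks, params) {
  if (nrow(bundles) == 0) {
    return(tibble(bundle_id = character(), key = character(), at = character(),
                  vertex = character(), gap = integer(), vtrack = integer(),
                  elev = integer(), zone = character(), width = numeric(),
                  dist = numeric()))
  }
  vt <- tracks$y
  ends <- bind_rows(lapply(c("from", "to"), function(side) {
    v <- bundles[[side]]
    vtrack <- as.integer(vt[v])
    other <- as.integer(vt[bundles[[if (side == "from") "to" else "from"]]])
    elev <- ifelse(is.na(bundles$route_track), other,
                   as.integer(bundles$route_track))
    tibble(bundle_id = bundles$bundle_id, key = bundles$key, at = side,
           vertex = v,
           gap = if (side == "from") bundles$gap_first else bundles$gap_last,
           vtrack = vtrack, elev = elev,
           zone = ifelse(elev == vtrack, "straight",
                         ifelse(elev < vtrack, "up", "down")),
           width = bundles$width,
           direction = bundles$direction)
  }))
  ends$dist <- NA_real_

  # up/down zones: shared rank space per (gap, track, zone); left vertex of
  # the gap (at == "from") first, then nearer elevations, forward first
  ud <- which(ends$zone != "straight")
  if (length(ud)) {
    grp <- paste(ends$gap[ud], ends$vtrack[ud], ends$zone[ud], sep = "|")
    for (idx in split(ud, grp)) {
      o <- order(ends$at[idx] != "from", abs(ends$elev[idx] - ends$vtrack[idx]),
                 ends$key[idx], ends$direction[idx] != "forward")
      idx <- idx[o]
      before <- cumsum(c(0, utils::head(ends$width[idx] + params$fs, -1)))
      ends$dist[idx] <- params$bs_border + before + ends$width[idx] / 2
    }
  }

  # straight zone: both ends of one edge run share one signed offset from the
  # row center; the forward bundle sits first
  str <- which(ends$zone == "straight")
  if (length(str)) {
    for (idx in split(str, ends$key[str])) {
      bid <- unique(ends$bundle_id[idx])
      binfo <- ends[idx[!duplicated(ends$bundle_id[idx])], ]
      o <- order(binfo$direction != "forward")
      binfo <- binfo[o, ]
      total <- sum(binfo$width) + params$fs * (nrow(binfo) - 1L)
      before <- cumsum(c(0, utils::head(binfo$width + params$fs, -1)))
      delta <- -total / 2 + before + binfo$width / 2
      names(delta) <- binfo$bundle_id
      ends$dist[idx] <- delta[ends$bundle_id[idx]]
    }
  }
  ends
}

# unique horizontal position (slot) for every vertical edge segment of each
# inter-layer gap.  Slot order follows the vertical position of the
# horizontal runs the segments connect (track first, then connection depth).
route_slots <- function(bundles, ends, params) {
  empty <- tibble(gap = integer(), bundle_id = character(), seg = character(),
                  width = numeric(), rank = integer())
  if (nrow(bundles) == 0) return(empty)
  i_from <- match(paste(bundles$bundle_id, "from"),
                  paste(ends$bundle_id, ends$at))
  i_to <- match(paste(bundles$bundle_id, "to"),
                paste(ends$bundle_id, ends$at))
  zf <- ends$zone[i_from]; zt <- ends$zone[i_to]
  df <- ends$dist[i_from]; dt <- ends$dist[i_to]

  mk <- function(sel, gap, seg, srt1) {
    tibble(gap = gap[sel], bundle_id = bundles$bundle_id[sel], seg = seg,
           width = bundles$width[sel],
           srt_track = ifelse(is.na(bundles$route_track[sel]), 0L,
                              bundles$route_track[sel]),
           srt1 = srt1[sel], key = bundles$key[sel],
           direction = bundles$direction[sel])
  }
  segs <- bind_rows(
    mk(bundles$span == 1L & zf != "straight", bundles$gap_first, "mid", df),
    mk(bundles$span > 1L & zf != "straight", bundles$gap_first, "first", df),
    mk(bundles$span > 1L & zt != "straight", bundles$gap_last, "last", dt)
  )
  if (nrow(segs) == 0) return(empty)
  out <- lapply(split(seq_len(nrow(segs)), segs$gap), function(idx) {
    o <- order(segs$srt_track[idx], segs$srt1[idx], segs$key[idx],
               segs$direction[idx] != "forward")
    res <- segs[idx[o], c("gap", "bundle_id", "seg", "width")]
    res$rank <- seq_len(nrow(res)) - 1L
    res
  })
  bind_rows(out)
}

#' Compute the two space parameters of the drawing
#'
#' `needed_vertex_height` is the uniform vertex height required so that every
#' vertex can stack its up-, straight- and down-zone connection points with
#' `fs` free space and `bs_border` border space; `needed_inter_layer_space`
#' is the horizontal gap width required so that every vertical edge segment
#' of the busiest inter-layer gap gets a unique slot.  Both are floored at
#' the configured minima.
#'
#' @param ends,slots Internal routing tables (see [gmsa_route_edges()]).
#' @param params A `gmsa_space_params`.
#' @return A list `needed_vertex_height`, `needed_inter_layer_space`.
#' @export
gmsa_compute_space_params <- function(ends, slots, params) {
  h <- params$min_vertex_height
  if (nrow(ends)) {
    per_vertex <- split(seq_len(nrow(ends)), ends$vertex)
    req <- map_dbl(per_vertex, function(idx) {
      up <- idx[ends$zone[idx] == "up"]
      dn <- idx[ends$zone[idx] == "down"]
      st <- idx[ends$zone[idx] == "straight"]
      ext <- function(ii) if (length(ii)) max(ends$dist[ii] + ends$width[ii] / 2) else 0
      st_tot <- if (length(st)) 2 * max(abs(ends$dist[st]) + ends$width[st] / 2) else 0
      ext(up) + ext(dn) + st_tot + 2 * params$fs
    })
    h <- max(h, req)
  }
  gapw <- params$min_inter_layer
  if (nrow(slots)) {
    per_gap <- split(slots$width, slots$gap)
    req <- map_dbl(per_gap, function(w) sum(w + params$fs) + 2 * params$bs_border)
    gapw <- max(gapw, req)
  }
  list(needed_vertex_height = h, needed_inter_layer_space = gapw)
}

#' Route all multi-edges orthogonally
#'
#' Runs the full routing stage: dummy chains are collapsed into drawable long
#' edges ([gmsa_collapse_dummies()]), parallel same-direction edges are
#' bundled ([gmsa_bundle_edges()]), connection points are placed in the up /
#' straight / down zones of the vertex borders, every vertical segment gets a
#' unique horizontal slot in its inter-layer gap, and the two global space
#' parameters are derived ([gmsa_compute_space_params()]).
#'
#' @param bs A `gmsa_blocksets`.
#' @param tracks Result of [gmsa_assign_tracks()].
#' @param params A `gmsa_space_params`.
#' @return An object of class `gmsa_routes`: `drawable`, `bundles`, `ends`,
#'   `slots`, `space`, `params`.
#' @export
gmsa_route_edges <- function(bs, tracks, params = gmsa_space_params()) {
  drawable <- gmsa_collapse_dummies(bs, tracks)
  bundles <- gmsa_bundle_edges(drawable, params)
  ends <- route_connections(bundles, tracks, params)
  slots <- route_slots(bundles, ends, params)
  space <- gmsa_compute_space_params(ends, slots, params)
  structure(list(drawable = drawable, bundles = bundles, ends = ends,
                 slots = slots, space = space, params = params),
            class = "gmsa_routes")
}

#' @export
print.gmsa_routes <- function(x, ...) {
  cat(sprintf(paste0("<gmsa_routes> %d drawable edges, %d bundles, ",
                     "%d vertical slots; vertex height %.0f px, ",
                     "inter-layer space %.0f px\n"),
              nrow(x$drawable), nrow(x$bundles), nrow(x$slots),
              x$space$needed_vertex_height, x$space$needed_inter_layer_space))
  invisible(x)
}
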