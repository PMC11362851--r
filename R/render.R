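# block-length dependent vertex width: log-scaled between the configured
# limits so multi-kb blocks stay on screen
vertex_width <- function(length_nt, l_max, params) {
  if (l_max <= 1) return(rep(params$min_vertex_width, length(length_nt)))
  w <- params$min_vertex_width +
    (params$max_vertex_width - params$min_vertex_width) *
    log10(pmax(length_nt, 1)) / log10(l_max)
  pmin(pmax(w, params$min_vertex_width), params$max_vertex_width)
}

# drop repeated and collinear points of an orthogonal polyline
simplify_polyline <- function(p) {
  keep <- c(TRUE, rowSums(abs(diff(p))) > 1e-9)
  p <- p[keep, , drop = FALSE]
  if (nrow(p) < 3) return(p)
  int <- seq(2, nrow(p) - 1)
  coll <- (p[int - 1, 1] == p[int, 1] & p[int, 1] == p[int + 1, 1]) |
          (p[int - 1, 2] == p[int, 2] & p[int, 2] == p[int + 1, 2])
  p[c(TRUE, !coll, TRUE), , drop = FALSE]
}

polyline_bends <- function(p) max(nrow(simplify_polyline(p)) - 2L, 0L)

# parallel offset of an orthogonal polyline: horizontal segments shift in y,
# vertical segments in x; corners are recomputed, endpoints keep their x on
# the vertex border (first/last segments are horizontal)
offset_polyline <- function(p, d) {
  if (d == 0 || nrow(p) < 2) return(p)
  n <- nrow(p)
  horiz <- p[-n, 2] == p[-1, 2]
  q <- p
  for (s in seq_len(n - 1L)) {
    if (horiz[s]) {
      q[s, 2] <- p[s, 2] + d; q[s + 1L, 2] <- p[s + 1L, 2] + d
    } else {
      q[s, 1] <- p[s, 1] + d; q[s + 1L, 1] <- p[s + 1L, 1] + d
    }
  }
  # re-join corners: a corner takes x from its vertical and y from its
  # horizontal segment
  if (n > 2) {
    for (k in seq(2, n - 1L)) {
      q[k, 1] <- p[k, 1] + if (horiz[k - 1L] && !horiz[k]) d else 0
      q[k, 2] <- p[k, 2] + if (!horiz[k - 1L] && horiz[k]) d else 0
      if (horiz[k - 1L] && horiz[k]) q[k, 2] <- p[k, 2] + d
      if (!horiz[k - 1L] && !horiz[k]) q[k, 1] <- p[k, 1] + d
    }
    q[1, 2] <- p[1, 2] + if (horiz[1]) d else 0
    q[1, 1] <- p[1, 1] + if (!horiz[1]) d else 0
    q[n, 2] <- p[n, 2] + if (horiz[n - 1L]) d else 0
    q[n, 1] <- p[n, 1] + if (!horiz[n - 1L]) d else 0
  }
  q
}

#' Compute the absolute geometry of the drawing
#'
#' Places the vertices on a grid -- layer columns as wide as the widest
#' vertex, tracks as rows of the uniform needed vertex height, vertices
#' horizontally centered in their column -- and transforms the relative edge
#' routes into absolute orthogonal polylines, one per bundled sequence
#' member.
#'
#' @param g The `gmsa_graph` being drawn.
#' @param layer Named layer vector (real vertices and dummies).
#' @param tracks Result of [gmsa_assign_tracks()].
#' @param routes A `gmsa_routes`.
#' @return An object of class `gmsa_geometry` with `vertices` (tibble `id`,
#'   `layer`, `track`, `x`, `y`, `w`, `h`, `cx`, `cy`, `merged`), `bundles`
#'   (with `points` and `bends`), `edges` (one polyline per bundled member,
#'   with the owning sequence and its color), `canvas` and the space/config
#'   actually used.
#' @export
gmsa_final_geometry <- function(g, layer, tracks, routes) {
  params <- routes$params
  ids <- g$blocks$id[g$blocks$id %in% names(tracks$y)]
  len <- g$blocks$length_nt[match(ids, g$blocks$id)]
  w <- vertex_width(len, max(len), params)
  col_width <- max(w)
  H <- routes$space$needed_vertex_height
  gapw <- routes$space$needed_inter_layer_space

  vl <- as.integer(layer[ids])
  vtrack <- as.integer(tracks$y[ids])
  all_tracks <- range(tracks$y)
  tmin <- all_tracks[1]
  x_left <- function(l) params$margin + l * (col_width + gapw)
  y_center <- function(t) params$margin + (t - tmin) * (H + params$vertex_gap_y) + H / 2
  cx <- x_left(vl) + col_width / 2
  cy <- y_center(vtrack)
  vertices <- tibble(
    id = ids, layer = vl, track = vtrack,
    x = cx - w / 2, y = cy - H / 2, w = w, h = H, cx = cx, cy = cy,
    merged = lengths(g$blocks$merged_from[match(ids, g$blocks$id)]) > 1L
  )

  vx <- stats::setNames(seq_len(nrow(vertices)), vertices$id)
  conn_y_vec <- function(kvert, zone, dist) {
    ifelse(zone == "up", vertices$y[kvert] + dist,
           ifelse(zone == "down", vertices$y[kvert] + vertices$h[kvert] - dist,
                  vertices$cy[kvert] + dist))
  }
  slot_x <- local({
    sx <- stats::setNames(numeric(0), character(0))
    for (idx in split(seq_len(nrow(routes$slots)), routes$slots$gap)) {
      sl <- routes$slots[idx, ]
      sl <- sl[order(sl$rank), ]
      gx <- x_left(sl$gap[1]) + col_width
      before <- cumsum(c(0, utils::head(sl$width + params$fs, -1)))
      sx[paste0(sl$bundle_id, "|", sl$seg)] <-
        gx + params$bs_border + before + sl$width / 2
    }
    sx
  })

  bnd <- routes$bundles
  ends <- routes$ends
  i_from <- match(paste(bnd$bundle_id, "from"), paste(ends$bundle_id, ends$at))
  i_to <- match(paste(bnd$bundle_id, "to"), paste(ends$bundle_id, ends$at))
  ku <- vx[bnd$from]; kv <- vx[bnd$to]
  y_from_all <- conn_y_vec(ku, ends$zone[i_from], ends$dist[i_from])
  y_to_all <- conn_y_vec(kv, ends$zone[i_to], ends$dist[i_to])
  x0_all <- vertices$x[ku] + vertices$w[ku]    # right border of u
  x1_all <- vertices$x[kv]                     # left border of v
  bpoints <- vector("list", nrow(bnd))
  for (k in seq_len(nrow(bnd))) {
    zf <- ends$zone[i_from[k]]; zt <- ends$zone[i_to[k]]
    y_from <- y_from_all[k]; y_to <- y_to_all[k]
    x0 <- x0_all[k]; x1 <- x1_all[k]
    bid <- bnd$bundle_id[k]
    if (bnd$span[k] == 1L) {
      if (zf == "straight") {
        p <- rbind(c(x0, y_from), c(x1, y_to))
      } else {
        s <- slot_x[[paste0(bid, "|mid")]]
        p <- rbind(c(x0, y_from), c(s, y_from), c(s, y_to), c(x1, y_to))
      }
    } else {
      run_y <- if (zf == "straight") y_from
               else if (zt == "straight") y_to
               else y_center(bnd$route_track[k])
      p <- rbind(c(x0, y_from))
      if (zf != "straight") {
        s1 <- slot_x[[paste0(bid, "|first")]]
        p <- rbind(p, c(s1, y_from), c(s1, run_y))
      }
      if (zt != "straight") {
        s2 <- slot_x[[paste0(bid, "|last")]]
        p <- rbind(p, c(s2, run_y), c(s2, y_to))
      }
      p <- rbind(p, c(x1, y_to))
    }
    bpoints[[k]] <- simplify_polyline(p)
  }
  bundles <- routes$bundles
  bundles$points <- bpoints
  bundles$bends <- map_int(bpoints, polyline_bends)

  seq_color <- stats::setNames(g$sequences$color, g$sequences$name)
  nm <- bundles$n_members
  reps <- rep(seq_len(nrow(bundles)), nm)
  offs <- unlist(lapply(nm, function(n) seq_len(n) - (n + 1) / 2)) *
    params$member_px
  mem <- unlist(bundles$members)
  edges <- tibble(
    bundle_id = bundles$bundle_id[reps], sequence = mem,
    direction = bundles$direction[reps],
    color = unname(seq_color[mem]),
    span = bundles$span[reps],
    bends = bundles$bends[reps],
    points = map2(reps, offs,
                  function(k, d) offset_polyline(bundles$points[[k]], d))
  )

  canvas <- c(width = x_left(max(vl)) + col_width + params$margin,
              height = y_center(all_tracks[2]) + H / 2 + params$margin)
  structure(list(vertices = vertices, bundles = bundles, edges = edges,
                 canvas = canvas, space = routes$space, params = params),
            class = "gmsa_geometry")
}

svg_fmt <- function(x) sprintf("%.2f", x)

#' Render a computed layout as a standalone SVG document
#'
#' Vertices are drawn as rectangles (blue for single alignment blocks,
#' orange for merged blocks), each bundled edge member as an individual
#' orthogonal polyline in its sequence's color so one contig stays traceable,
#' with a small arrowhead at the head of the original direction.  Inside
#' each vertex, directional glyphs (colored arrows) show each aligned
#' contig's reading direction -- rightward for plus strand, leftward for
#' minus, double-headed when a merged vertex contains both -- and triangular
#' start/end flags mark each contig's first and last vertex.
#'
#' @param geom A `gmsa_geometry`.
#' @param g The `gmsa_graph` that was laid out.
#' @param path Optional output file; when given, the SVG is written there.
#' @return An `xml2::xml_document`, invisibly when `path` is given.
#' @export
gmsa_render_svg <- function(geom, g, path = NULL) {
  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg", version = "1.1",
    width = svg_fmt(geom$canvas[["width"]]),
    height = svg_fmt(geom$canvas[["height"]]),
    viewBox = paste("0 0", svg_fmt(geom$canvas[["width"]]),
                    svg_fmt(geom$canvas[["height"]]))
  )
  xml2::xml_add_child(doc, "rect", x = "0", y = "0", width = "100%",
                      height = "100%", fill = "white", class = "background")

  v <- geom$vertices
  for (k in seq_len(nrow(v))) {
    xml2::xml_add_child(doc, "rect", class = "vertex",
                        id = paste0("vertex-", v$id[k]),
                        x = svg_fmt(v$x[k]), y = svg_fmt(v$y[k]),
                        width = svg_fmt(v$w[k]), height = svg_fmt(v$h[k]),
                        fill = if (v$merged[k]) "orange" else "steelblue",
                        stroke = "black", `stroke-width` = "0.5")
  }

  for (k in seq_len(nrow(geom$edges))) {
    p <- geom$edges$points[[k]]
    pts <- paste(paste(svg_fmt(p[, 1]), svg_fmt(p[, 2]), sep = ","),
                 collapse = " ")
    xml2::xml_add_child(doc, "polyline", class = "edge",
                        `data-sequence` = geom$edges$sequence[k],
                        `data-direction` = geom$edges$direction[k],
                        points = pts, fill = "none",
                        stroke = geom$edges$color[k],
                        `stroke-width` = svg_fmt(geom$params$member_px))
    # arrowhead at the head of the original direction
    n <- nrow(p)
    if (geom$edges$direction[k] == "forward") {
      tip <- p[n, ]; base <- p[n - 1L, ]
    } else {
      tip <- p[1, ]; base <- p[2, ]
    }
    d <- tip - base
    d <- d / max(sqrt(sum(d^2)), 1e-9) * 4
    o <- c(-d[2], d[1]) / 2
    tri <- rbind(tip, tip - d + o, tip - d - o)
    xml2::xml_add_child(doc, "polygon", class = "arrow",
                        points = paste(paste(svg_fmt(tri[, 1]),
                                             svg_fmt(tri[, 2]), sep = ","),
                                       collapse = " "),
                        fill = geom$edges$color[k])
  }

  # directional glyphs and start/end flags
  seq_tbl <- g$sequences
  vx <- stats::setNames(seq_len(nrow(v)), v$id)
  for (s in seq_len(nrow(seq_tbl))) {
    col <- seq_tbl$color[s]
    gn <- seq_tbl$genome[s]; cg <- seq_tbl$contig[s]
    vs <- seq_tbl$vertices[[s]]
    for (id in vs) {
      k <- vx[[id]]
      rows <- g$blocks$rows[[match(id, g$blocks$id)]]
      sg <- unique(rows$sigma[rows$genome == gn & rows$contig == cg])
      if (length(sg) == 0) next
      gy <- v$y[k] + 3 + (s - 1) * 4
      gx1 <- v$cx[k] - 6; gx2 <- v$cx[k] + 6
      xml2::xml_add_child(doc, "line", class = "glyph",
                          `data-sequence` = seq_tbl$name[s],
                          x1 = svg_fmt(gx1), y1 = svg_fmt(gy),
                          x2 = svg_fmt(gx2), y2 = svg_fmt(gy),
                          stroke = col, `stroke-width` = "1")
      heads <- character(0)
      if (any(sg == 1)) heads <- c(heads, "right")
      if (any(sg == -1)) heads <- c(heads, "left")
      for (hd in heads) {
        if (hd == "right") {
          tri <- rbind(c(gx2 + 3, gy), c(gx2, gy - 2), c(gx2, gy + 2))
        } else {
          tri <- rbind(c(gx1 - 3, gy), c(gx1, gy - 2), c(gx1, gy + 2))
        }
        xml2::xml_add_child(doc, "polygon",
                            class = if (length(heads) == 2) "glyph-head-double"
                                    else "glyph-head",
                            points = paste(paste(svg_fmt(tri[, 1]),
                                                 svg_fmt(tri[, 2]), sep = ","),
                                           collapse = " "),
                            fill = col)
      }
    }
    # triangular start/end flags on the sequence's first and last vertex
    for (which_end in c("start", "end")) {
      id <- if (which_end == "start") vs[1] else vs[length(vs)]
      k <- vx[[id]]
      fy <- v$y[k] - 2 - (s - 1) * 5
      fx <- v$x[k] + 2 + (s - 1) * 3
      tri <- if (which_end == "start") {
        rbind(c(fx, fy - 4), c(fx + 5, fy - 2), c(fx, fy))
      } else {
        rbind(c(fx + 5, fy - 4), c(fx, fy - 2), c(fx + 5, fy))
      }
      xml2::xml_add_child(doc, "polygon", class = paste0("flag-", which_end),
                          `data-sequence` = seq_tbl$name[s],
                          points = paste(paste(svg_fmt(tri[, 1]),
                                               svg_fmt(tri[, 2]), sep = ","),
                                         collapse = " "),
                          fill = col, stroke = col)
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}
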