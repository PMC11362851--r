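#' Compute the complete layered layout of a gMSA graph
#'
#' Runs the full layout pipeline on a validated graph: optional guide-range
#' extraction, trimming to guide anchors, co-linear block merging, cycle
#' removal into a single-source/single-sink DAG, longest-path layering with
#' dummy-vertex properization, crossing reduction by global sifting of
#' block-sets, vertical track stacking, orthogonal multi-edge routing and
#' final geometry.
#'
#' @param g A `gmsa_graph`.
#' @param range Optional `c(start_nt, end_nt)` restriction on the guide.
#' @param merge Merge co-linear blocks first (default `TRUE`).
#' @param rounds Sifting rounds (default 10; 0 disables crossing reduction).
#' @param strict_otherwise_reverse Passed to [gmsa_build_dag()].
#' @param params A [gmsa_space_params()] configuration.
#' @return An object of class `gmsa_layout` holding every intermediate stage
#'   (`graph`, `dag`, `layer`, `proper`, `blocksets`, `sift`, `tracks`,
#'   `routes`, `geometry`) and a machine-readable `report` (see
#'   [glance.gmsa_layout()]).
#' @examples
#' g <- gmsa_synth(n_guide_vertices = 8, n_comparative = 2, seed = 7)
#' ly <- gmsa_layout(g)
#' glance(ly)
#' @export
gmsa_layout <- function(g, range = NULL, merge = TRUE, rounds = 10,
                        strict_otherwise_reverse = FALSE,
                        params = gmsa_space_params()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("layout stage `", name, "` failed: ", conditionMessage(e)))
    })
  }
  viol <- gmsa_validate(g)
  if (nrow(viol) > 0) {
    abort(c("invalid input graph:",
            stats::setNames(paste(viol$rule, "--", viol$detail),
                            rep("x", nrow(viol)))))
  }
  if (!is.null(range)) {
    g <- stage("extract_range", gmsa_extract_range(g, range[1], range[2]))
  }
  g <- stage("trim_to_guide", gmsa_trim_to_guide(g))
  if (merge) g <- stage("merge_colinear", gmsa_merge_colinear(g))
  dag <- stage("cycle_removal",
               gmsa_build_dag(g, strict_otherwise_reverse = strict_otherwise_reverse))
  layer <- stage("layering", gmsa_assign_layers(dag))
  proper <- stage("properize", gmsa_make_proper(dag, layer))
  bs <- stage("block_sets", gmsa_block_sets(proper))
  sift <- stage("ordering", gmsa_global_sift(bs, rounds = rounds))
  tracks <- stage("coordinates", gmsa_assign_tracks(bs, sift))
  routes <- stage("routing", gmsa_route_edges(bs, tracks, params))
  geometry <- stage("render_geometry",
                    gmsa_final_geometry(g, proper$layer, tracks, routes))

  direct <- geometry$bundles$span == 1L
  report <- tibble(
    n_vertices = length(dag$vertices),
    n_merged_vertices = sum(lengths(g$blocks$merged_from) > 1L),
    n_sequences = nrow(g$sequences),
    n_multiedges = gmsa_n_multiedges(g),
    n_dag_edges = nrow(dag$edges),
    n_bypaths = nrow(dag$bypaths) - 1L,
    n_reversed_bypaths = sum(dag$bypaths$reversed),
    n_dummy_vertices = length(proper$dummies),
    n_block_sets = nrow(bs$sets),
    crossings_before = sift$crossings[1],
    crossings_after = sift$crossings[length(sift$crossings)],
    n_tracks = length(unique(tracks$track[bs$sets$set_id])),
    max_bends_direct = if (any(direct)) max(geometry$bundles$bends[direct]) else 0L,
    max_bends_long = if (any(!direct)) max(geometry$bundles$bends[!direct]) else 0L,
    n_drawn_edges = nrow(geometry$edges)
  )
  structure(list(graph = g, dag = dag, layer = layer, proper = proper,
                 blocksets = bs, sift = sift, tracks = tracks,
                 routes = routes, geometry = geometry, report = report),
            class = "gmsa_layout")
}

#' @export
print.gmsa_layout <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<gmsa_layout> %d vertices on %d layers / %d tracks; ",
                     "%d bypaths (%d reversed), %d dummies\n",
                     "  crossings %d -> %d; %d drawn edges; ",
                     "max bends direct %d, long %d\n"),
              r$n_vertices, max(x$layer) + 1L, r$n_tracks, r$n_bypaths,
              r$n_reversed_bypaths, r$n_dummy_vertices, r$crossings_before,
              r$crossings_after, r$n_drawn_edges, r$max_bends_direct,
              r$max_bends_long))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gMSA layout into coordinate tables
#'
#' @param x A `gmsa_layout`.
#' @param what `"vertices"` (default): one row per drawn vertex with grid and
#'   pixel coordinates; `"edges"`: one row per individually drawn edge
#'   polyline (one per bundled sequence member) with its points unnested;
#'   `"bundles"`: one row per bundled edge with bend counts.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gmsa_layout <- function(x, what = c("vertices", "edges", "bundles"), ...) {
  what <- match.arg(what)
  if (what == "vertices") {
    return(x$geometry$vertices)
  }
  if (what == "bundles") {
    b <- x$geometry$bundles
    return(tibble(bundle_id = b$bundle_id, from = b$from, to = b$to,
                  span = b$span, direction = b$direction,
                  n_members = b$n_members, width = b$width, bends = b$bends))
  }
  e <- x$geometry$edges
  bind_rows(lapply(seq_len(nrow(e)), function(k) {
    p <- e$points[[k]]
    tibble(bundle_id = e$bundle_id[k], sequence = e$sequence[k],
           direction = e$direction[k], color = e$color[k],
           span = e$span[k], bends = e$bends[k],
           point = seq_len(nrow(p)), x = p[, 1], y = p[, 2])
  }))
}

#' One-row summary of a gMSA layout
#'
#' Counts reported by the pipeline: vertices, merged vertices, bypaths and
#' how many were reversed during cycle removal, dummy vertices, crossings
#' before and after sifting, tracks used, bend maxima and the number of
#' individually drawn edges.
#'
#' @param x A `gmsa_layout`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.gmsa_layout <- function(x, ...) x$report

#' Plot a gMSA layout with ggplot2
#'
#' @param object A `gmsa_layout`.
#' @param ... Unused.
#' @return A ggplot object mirroring the SVG drawing: vertex rectangles
#'   (orange = merged blocks) and one orthogonal polyline per sequence
#'   member.
#' @export
autoplot.gmsa_layout <- function(object, ...) {
  v <- object$geometry$vertices
  e <- tidy(object, "edges")
  e$grp <- paste(e$bundle_id, e$sequence)
  ggplot2::ggplot() +
    ggplot2::geom_path(data = e,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$grp, colour = .data$color)) +
    ggplot2::geom_rect(data = v,
                       ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                                    ymin = .data$y, ymax = .data$y + .data$h,
                                    fill = .data$merged),
                       colour = "black", linewidth = 0.2) +
    ggplot2::scale_colour_identity() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "orange"), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' Run the file-to-file layout pipeline
#'
#' Thin wrapper used by the command line interface: reads a graph (JSON or
#' MAF), lays it out, writes the SVG and optionally a JSON report of the
#' pipeline counts.
#'
#' @param input Input file (`.json` or `.maf`).
#' @param output Output SVG path.
#' @param report Optional path for a JSON report.
#' @param guide,range,rounds,merge,strict_otherwise_reverse,params See
#'   [read_gmsa()] and [gmsa_layout()].
#' @return The `gmsa_layout`, invisibly.
#' @export
gmsa_pipeline <- function(input, output, report = NULL, guide = NULL,
                          range = NULL, rounds = 10, merge = TRUE,
                          strict_otherwise_reverse = FALSE,
                          params = gmsa_space_params()) {
  g <- read_gmsa(input, guide = guide)
  ly <- gmsa_layout(g, range = range, merge = merge, rounds = rounds,
                    strict_otherwise_reverse = strict_otherwise_reverse,
                    params = params)
  gmsa_render_svg(ly$geometry, ly$graph, path = output)
  if (!is.null(report)) {
    jsonlite::write_json(as.list(ly$report), report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(ly)
}
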