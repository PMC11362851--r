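#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr bind_rows
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2
NULL

#' Build a gMSA graph from a block table and a sequence table
#'
#' A gMSA graph represents a genome-wide multiple sequence alignment as a
#' directed multi-graph: every vertex is an alignment block (a set of aligned
#' sequence intervals, possibly several blocks merged into one), and every
#' contig contributes a *vertex sequence* -- its total order over the blocks
#' it traverses.  The first sequence is the *guide sequence*; all remaining
#' (*comparative*) sequences must start and end on a guide vertex, so that no
#' loose ends dangle off the comparison.
#'
#' @param blocks A tibble with columns `id` (character), `length_nt` (numeric,
#'   representative block length in nucleotides), `merged_from` (list of
#'   character; the original block ids, length 1 for unmerged blocks) and
#'   `rows` (list of tibbles with columns `genome`, `contig`, `i`, `j`,
#'   `sigma`; 1-based inclusive coordinates, `sigma` is +1 or -1).
#' @param sequences A tibble with columns `name`, `genome`, `contig`, `color`
#'   and `vertices` (list of character block ids).  Row 1 is the guide; the
#'   remaining row order is the genome order (decreasing relevance).
#' @param check If `TRUE` (default), abort when [gmsa_validate()] reports
#'   violations.
#' @return An object of class `gmsa_graph`.
#' @seealso [gmsa_validate()], [gmsa_synth()], [read_gmsa()]
#' @export
gmsa_graph <- function(blocks, sequences, check = TRUE) {
  blocks <- as_tibble(blocks)
  sequences <- as_tibble(sequences)
  need_b <- c("id", "length_nt", "merged_from", "rows")
  need_s <- c("name", "genome", "contig", "color", "vertices")
  if (!all(need_b %in% names(blocks))) {
    abort(paste0("`blocks` must have columns: ", paste(need_b, collapse = ", ")))
  }
  if (!all(need_s %in% names(sequences))) {
    abort(paste0("`sequences` must have columns: ", paste(need_s, collapse = ", ")))
  }
  g <- structure(list(blocks = blocks, sequences = sequences),
                 class = "gmsa_graph")
  if (check) {
    v <- gmsa_validate(g)
    if (nrow(v) > 0) {
      abort(c("invalid gMSA graph:",
              stats::setNames(paste(v$rule, "--", v$detail), rep("x", nrow(v)))))
    }
  }
  g
}

#' @export
print.gmsa_graph <- function(x, ...) {
  ns <- nrow(x$sequences)
  cat(sprintf("<gmsa_graph> %d blocks (%d merged), %d sequences (guide: %s)\n",
              nrow(x$blocks), sum(lengths(x$blocks$merged_from) > 1L),
              ns, if (ns) x$sequences$name[1] else "<none>"))
  if (ns) {
    lens <- lengths(x$sequences$vertices)
    cat(sprintf("  %s: %d vertices\n", x$sequences$name, lens), sep = "")
  }
  invisible(x)
}

# id of every vertex on the guide sequence
guide_vertices <- function(g) g$sequences$vertices[[1]]

# total multi-edge (adjacency) count: sum over sequences of |S| - 1
#' Number of multi-edges (sequence adjacencies) of a gMSA graph
#'
#' Each consecutive pair of blocks in a vertex sequence is one directed edge of
#' the multi-graph; the total is the number of individually drawn edges in the
#' final layout.
#' @param g A `gmsa_graph`.
#' @return Integer count.
#' @export
gmsa_n_multiedges <- function(g) sum(pmax(lengths(g$sequences$vertices) - 1L, 0L))

#' Validate a gMSA graph
#'
#' Checks every structural invariant of the data model and returns the
#' violations as data rather than raising conditions: interval sanity
#' (`i <= j`, strand in \{-1, +1\}), non-empty blocks, the single-hit rule (a
#' contig may occur in at most one row of an unmerged block), sequences being
#' paths of at least two pairwise distinct vertices over existing blocks, and
#' the anchoring rule (every comparative sequence starts and ends on a guide
#' vertex).
#'
#' Merged blocks keep the constituent rows of the blocks they were merged
#' from, so the single-hit check is applied to unmerged blocks only.
#'
#' @param g A `gmsa_graph`.
#' @return A tibble with columns `rule`, `where`, `detail`; zero rows iff the
#'   graph is valid.
#' @export
gmsa_validate <- function(g) {
  v <- list()
  bad <- function(rule, where, detail) {
    v[[length(v) + 1L]] <<- tibble(rule = rule, where = where, detail = detail)
  }
  ids <- g$blocks$id
  if (anyDuplicated(ids)) {
    bad("unique-block-ids", "blocks", "duplicated block ids")
  }
  for (k in seq_len(nrow(g$blocks))) {
    id <- g$blocks$id[k]
    rows <- g$blocks$rows[[k]]
    mf <- g$blocks$merged_from[[k]]
    if (is.null(rows) || nrow(rows) == 0) {
      bad("rows-nonempty", id, "block has no sequence-interval rows")
      next
    }
    if (any(rows$i > rows$j)) {
      bad("interval-order", id, "row with start > end (i > j)")
    }
    if (!all(rows$sigma %in% c(-1, 1))) {
      bad("strand", id, "sigma must be +1 or -1")
    }
    if (g$blocks$length_nt[k] < 1) {
      bad("length-positive", id, "length_nt < 1")
    }
    if (length(mf) < 1L) {
      bad("merged-from", id, "merged_from must list at least one origin")
    }
    if (length(mf) == 1L) {
      ctg <- paste(rows$genome, rows$contig, sep = ":")
      if (anyDuplicated(ctg)) {
        bad("single-hit", id, "contig occurs in two rows of one unmerged block")
      }
    }
  }
  if (nrow(g$sequences) == 0) {
    bad("has-guide", "sequences", "graph has no sequences")
    return(bind_rows(v) %||% tibble(rule = character(), where = character(),
                                    detail = character()))
  }
  gv <- guide_vertices(g)
  for (k in seq_len(nrow(g$sequences))) {
    nm <- g$sequences$name[k]
    vs <- g$sequences$vertices[[k]]
    if (length(vs) < 2L) {
      bad("path-length", nm, "vertex sequence shorter than 2")
      next
    }
    if (anyDuplicated(vs)) {
      bad("path-distinct", nm, "vertex sequence revisits a vertex (not a path)")
    }
    missing <- setdiff(vs, ids)
    if (length(missing)) {
      bad("vertex-exists", nm,
          paste0("unknown block id(s): ", paste(missing, collapse = ", ")))
    }
    if (k > 1L && !(vs[1] %in% gv && vs[length(vs)] %in% gv)) {
      bad("anchoring", nm,
          "comparative sequence must start and end on a guide vertex")
    }
  }
  out <- bind_rows(v)
  if (is.null(out) || nrow(out) == 0) {
    tibble(rule = character(), where = character(), detail = character())
  } else {
    out
  }
}

#' Flatten a gMSA graph to one row per sequence interval
#'
#' Convenience view for TSV export and quick inspection: every aligned
#' interval of every block becomes one row.
#' @param g A `gmsa_graph`.
#' @return A tibble with columns `block_id`, `merged`, `length_nt`, `genome`,
#'   `contig`, `i`, `j`, `sigma`.
#' @export
gmsa_flat <- function(g) {
  bind_rows(lapply(seq_len(nrow(g$blocks)), function(k) {
    rows <- g$blocks$rows[[k]]
    tibble(block_id = g$blocks$id[k],
           merged = lengths(g$blocks$merged_from[k]) > 1L,
           length_nt = g$blocks$length_nt[k],
           genome = rows$genome, contig = rows$contig,
           i = rows$i, j = rows$j, sigma = rows$sigma)
  }))
}

# cheap tibble constructor for hot paths (no recycling or name checking)
fast_tbl <- function(...) {
  cols <- list(...)
  structure(cols, class = c("tbl_df", "tbl", "data.frame"),
            row.names = .set_row_names(length(cols[[1]])))
}

# deterministic default palette; guide red, then the comparative colors used
# throughout the package's drawings
gmsa_palette <- function(n) {
  base <- c("red", "green", "purple", "pink", "brown",
            "steelblue", "darkorange", "turquoise", "olive", "navy")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("color", seq_len(n - length(base))))
}
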