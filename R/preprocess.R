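# which sequence names traverse each vertex; named list id -> character vector
sequence_sets <- function(g) {
  env <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(g$sequences))) {
    nm <- g$sequences$name[k]
    for (v in g$sequences$vertices[[k]]) {
      env[[v]] <- c(env[[v]], nm)
    }
  }
  env
}

#' Merge co-linear alignment blocks
#'
#' Two adjacent blocks can be represented by one merged vertex when no
#' information is lost: they must be traversed by exactly the same set of
#' sequences, and every one of those sequences must traverse them
#' consecutively in the same order.  Maximal such runs are collapsed to a
#' single merged block whose `merged_from` lists the originals and whose
#' `length_nt` is the sum; the merged block keeps all constituent interval
#' rows (so per-constituent strands remain available for directional glyphs).
#' Merging stops early rather than shortening any sequence below two
#' vertices, and runs to a fixpoint, so the operation is idempotent.
#'
#' @param g A `gmsa_graph`.
#' @return A `gmsa_graph` with maximal co-linear runs merged.
#' @export
gmsa_merge_colinear <- function(g) {
  pair_mergeable <- function(g, sets, u, v) {
    su <- sort(sets[[u]]); sv <- sort(sets[[v]])
    if (!identical(su, sv)) return(FALSE)
    # every traversing sequence must visit v immediately after u,
    # and must keep >= 2 vertices after the merge
    for (nm in su) {
      w <- g$sequences$vertices[[match(nm, g$sequences$name)]]
      if (length(w) - 1L < 2L) return(FALSE)
      iu <- match(u, w)
      if (is.na(iu) || iu == length(w) || w[iu + 1L] != v) return(FALSE)
    }
    TRUE
  }
  repeat {
    found <- FALSE
    sets <- sequence_sets(g)
    for (k in seq_len(nrow(g$sequences))) {
      p <- 1L
      while (p < length(g$sequences$vertices[[k]])) {
        vs <- g$sequences$vertices[[k]]
        u <- vs[p]; v <- vs[p + 1L]
        if (pair_mergeable(g, sets, u, v)) {
          g <- merge_pair(g, u, v)
          sets[[paste(u, v, sep = "+")]] <- sets[[u]]
          found <- TRUE
          p <- max(p - 1L, 1L)
        } else {
          p <- p + 1L
        }
      }
    }
    if (!found) break
  }
  g
}

merge_pair <- function(g, u, v) {
  ku <- match(u, g$blocks$id); kv <- match(v, g$blocks$id)
  mid <- paste(u, v, sep = "+")
  merged <- tibble(
    id = mid,
    length_nt = g$blocks$length_nt[ku] + g$blocks$length_nt[kv],
    merged_from = list(c(g$blocks$merged_from[[ku]], g$blocks$merged_from[[kv]])),
    rows = list(bind_rows(g$blocks$rows[[ku]], g$blocks$rows[[kv]]))
  )
  g$blocks <- bind_rows(g$blocks[-c(ku, kv), ], merged)
  g$sequences$vertices <- map(g$sequences$vertices, function(w) {
    iu <- match(u, w)
    if (is.na(iu)) return(w)
    append(w[-c(iu, iu + 1L)], mid, after = iu - 1L)
  })
  g
}

#' Trim comparative sequences to their guide anchors
#'
#' Cuts every comparative sequence to its maximal sub-path whose first and
#' last vertices lie on the guide, enforcing the anchoring rule (no loose
#' ends).  Sequences left with fewer than two vertices -- including those
#' sharing no vertex with the guide -- are dropped with a warning.  Blocks no
#' longer referenced by any sequence are removed.
#'
#' @param g A `gmsa_graph`.
#' @return A `gmsa_graph` whose comparative sequences are guide-anchored.
#' @export
gmsa_trim_to_guide <- function(g) {
  gv <- guide_vertices(g)
  keep <- rep(TRUE, nrow(g$sequences))
  for (k in seq_len(nrow(g$sequences))[-1]) {
    vs <- g$sequences$vertices[[k]]
    on_guide <- which(vs %in% gv)
    if (length(on_guide) == 0) {
      warn(paste0("dropping sequence `", g$sequences$name[k],
                  "`: shares no vertex with the guide"))
      keep[k] <- FALSE
      next
    }
    vs <- vs[on_guide[1]:on_guide[length(on_guide)]]
    if (length(vs) < 2L) {
      warn(paste0("dropping sequence `", g$sequences$name[k],
                  "`: fewer than 2 vertices after trimming"))
      keep[k] <- FALSE
      next
    }
    g$sequences$vertices[[k]] <- vs
  }
  g$sequences <- g$sequences[keep, ]
  used <- unique(unlist(g$sequences$vertices))
  g$blocks <- g$blocks[g$blocks$id %in% used, ]
  g
}

#' Restrict a gMSA graph to a guide nucleotide range
#'
#' Keeps only guide vertices whose interval on the guide contig overlaps
#' `[start_nt, end_nt]` (inclusive on both ends), removes the dropped guide
#' vertices from every sequence, and re-trims the comparative sequences so
#' they anchor inside the restriction.
#'
#' @param g A `gmsa_graph`.
#' @param start_nt,end_nt 1-based inclusive bounds on the guide contig.
#' @return A `gmsa_graph` restricted to the range.
#' @export
gmsa_extract_range <- function(g, start_nt, end_nt) {
  if (start_nt > end_nt) abort("start_nt must be <= end_nt")
  gg <- g$sequences$genome[1]; gc <- g$sequences$contig[1]
  gv <- guide_vertices(g)
  overlaps <- map_lgl(gv, function(v) {
    rows <- g$blocks$rows[[match(v, g$blocks$id)]]
    r <- rows[rows$genome == gg & rows$contig == gc, ]
    any(r$i <= end_nt & r$j >= start_nt)
  })
  kept <- gv[overlaps]
  if (length(kept) < 2L) {
    abort(sprintf("range %s..%s leaves %d guide vertices (need >= 2)",
                  format(start_nt), format(end_nt), length(kept)))
  }
  dropped <- setdiff(gv, kept)
  g$sequences$vertices <- map(g$sequences$vertices, function(w) {
    w[!w %in% dropped]
  })
  g <- gmsa_trim_to_guide(g)
  v <- gmsa_validate(g)
  if (nrow(v) > 0) {
    abort(c("range extraction produced an invalid graph:",
            stats::setNames(paste(v$rule, "--", v$detail), rep("x", nrow(v)))))
  }
  g
}
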