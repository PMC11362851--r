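#' Stack block-sets onto vertical tracks
#'
#' Assigns every block-set an integer track: the guide block-set sits on
#' track 0, tracks above the guide are negative, tracks below positive.  In
#' two symmetric passes the sifted order is walked away from the guide --
#' first from the block-set just above the guide up to the top, then from the
#' one just below down to the bottom -- and each block-set is stacked on the
#' free track closest to the guide on which it does not intersect an already
#' placed block-set.  Intersection means overlap of the layer hulls
#' `[layer_min, layer_max]`; because sets are processed guide-outwards in
#' sifted order, overlapping sets keep their relative order and no new edge
#' crossings arise.  All vertices of a block-set share its track, which keeps
#' the guide linear and bypath runs horizontally aligned.
#'
#' @param bs A `gmsa_blocksets`.
#' @param sift Result of [gmsa_global_sift()] (needs `order` and `index_gs`).
#' @return A list: `track` (integer vector indexed by set_id), `y` (named
#'   vertex -> track of its block-set).
#' @export
gmsa_assign_tracks <- function(bs, sift) {
  ord <- sift$order
  igs <- sift$index_gs
  n <- length(ord)
  track <- integer(max(ord))
  track[ord[igs]] <- 0L
  hull <- function(s) c(bs$sets$layer_min[match(s, bs$sets$set_id)],
                        bs$sets$layer_max[match(s, bs$sets$set_id)])
  occupants <- list(`0` = list(hull(ord[igs])))
  place <- function(s, side) {
    h <- hull(s)
    t <- side
    repeat {
      key <- as.character(t)
      occ <- occupants[[key]]
      clash <- any(map_lgl(occ %||% list(),
                           function(o) h[1] <= o[2] && o[1] <= h[2]))
      if (!clash) break
      t <- t + side
    }
    track[s] <<- t
    occupants[[as.character(t)]] <<- c(occupants[[as.character(t)]], list(h))
  }
  if (igs > 1L) for (k in rev(seq_len(igs - 1L))) place(ord[k], -1L)
  if (igs < n) for (k in (igs + 1L):n) place(ord[k], +1L)
  y <- track[bs$vertex_set]
  names(y) <- names(bs$vertex_set)
  list(track = track, y = y)
}
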