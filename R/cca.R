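## Connected-component labelling and hole filling on 2D/3D logical lattices.
## Vectorised frontier BFS; supports 4/8 connectivity in 2D and 6/18/26 in 3D.

neighbour_offsets <- function(ndim, connectivity) {
  steps <- as.matrix(expand.grid(rep(list(-1L:1L), ndim)))
  ord <- rowSums(abs(steps))
  keep <- switch(as.character(connectivity),
                 "4" = ord == 1, "8" = ord >= 1,
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2, "26" = ord >= 1,
                 stop("unsupported connectivity: ", connectivity, call. = FALSE))
  steps[keep, , drop = FALSE]
}

#' Label connected components of a binary lattice
#'
#' Works on 2D matrices (connectivity 4 or 8) and 3D arrays (6, 18 or 26).
#' Labels are assigned in scan order of each component's first voxel and are
#' therefore deterministic for a given geometry.
#'
#' @param mask Logical matrix or 3D array.
#' @param connectivity 4/8 (2D) or 6/18/26 (3D).
#' @return Integer array of the same shape; 0 = background, components 1..K.
#' @export
cc_label <- function(mask, connectivity = if (length(dim(mask)) == 2L) 8L else 26L) {
  d <- dim(mask)
  nd <- length(d)
  if (!(nd %in% c(2L, 3L))) stop("mask must be 2D or 3D", call. = FALSE)
  offs <- neighbour_offsets(nd, connectivity)
  # linear-index deltas plus per-axis coordinate deltas for bounds guarding
  strides <- cumprod(c(1L, d[-nd]))
  lin_delta <- as.integer(offs %*% strides)
  labels <- array(0L, d)
  todo <- which(mask)
  if (length(todo) == 0L) return(labels)
  coord <- arrayInd(todo, d)
  # coordinate lookup per foreground voxel, keyed by linear index
  coord_of <- matrix(0L, nrow = prod(d), ncol = nd)
  coord_of[todo, ] <- coord
  inmask <- logical(prod(d))
  inmask[todo] <- TRUE
  nextlab <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    nextlab <- nextlab + 1L
    labels[seed] <- nextlab
    frontier <- seed
    while (length(frontier) > 0L) {
      fc <- coord_of[frontier, , drop = FALSE]
      cand <- rep(frontier, each = nrow(offs)) +
        rep(lin_delta, times = length(frontier))
      # bounds guard: neighbour coordinates must stay on the lattice
      ok <- rep(TRUE, length(cand))
      for (axis in seq_len(nd)) {
        cc <- rep(fc[, axis], each = nrow(offs)) + rep(offs[, axis], times = length(frontier))
        ok <- ok & cc >= 1L & cc <= d[axis]
      }
      cand <- cand[ok]
      cand <- cand[inmask[cand] & labels[cand] == 0L]
      if (length(cand) == 0L) break
      cand <- unique(cand)
      labels[cand] <- nextlab
      frontier <- cand
    }
  }
  labels
}

#' Fill enclosed holes in a binary lattice
#'
#' A hole is a background component that does not touch the lattice border.
#' 2D masks use 4-connected background, 3D masks 6-connected (the standard
#' complementary connectivities for 8- and 26-connected foregrounds).
#'
#' @param mask Logical matrix or 3D array.
#' @return Logical array with holes filled.
#' @export
fill_holes <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  if (nd == 2L) {
    # EBImage's fillHull implements exactly this for 2D
    return(EBImage::fillHull(mask) > 0)
  }
  bg <- cc_label(!mask, connectivity = 6L)
  if (max(bg) == 0L) return(mask)
  border_labels <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                            bg[, , 1], bg[, , d[3]]))
  mask | (bg != 0L & !(bg %in% border_labels))
}

## Keep the connected component(s) of `mask` containing any of `seeds`
## (linear indices). Returns logical array.
keep_components_with <- function(mask, seeds, connectivity = if (length(dim(mask)) == 2L) 8L else 26L) {
  lab <- cc_label(mask, connectivity)
  hit <- unique(lab[seeds])
  hit <- hit[hit != 0L]
  if (length(hit) == 0L) return(array(FALSE, dim(mask)))
  array(lab %in% hit, dim(mask))
}
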