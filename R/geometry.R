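#' @title 2D axis geometry on binary masks
#'
#' @description Geometry primitives behind the simulated drawing of long and
#' short axes: boundary extraction, the true longest axis (maximum-distance
#' boundary pair, the RECIST-style longest diameter), a PCA ellipse fit, the
#' medially positioned long axis (longest chord parallel to the ellipse's
#' major axis), the perpendicular short axis, and the angularly spaced
#' boundary candidate sets used by the statistical axis search.
#'
#' In-plane points are `(row, col)` pairs of the plane's 2D matrix; lengths
#' are in mm under the plane's pixel spacing.
#' @name axis_geometry
NULL

#' Construct a 2D axis line (a simulated user drag)
#'
#' @param p0,p1 Length-2 in-plane endpoints `(row, col)`; may be fractional.
#' @param spacing In-plane pixel spacing (mm), length 2.
#' @param plane Optional plane tag (`"axial"`, `"coronal"`, `"sagittal"`).
#' @return An `axis_line2d` with fields `p0`, `p1`, `length_mm`, `plane`.
#' @export
axis_line <- function(p0, p1, spacing = c(1, 1), plane = NULL) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  structure(list(p0 = p0, p1 = p1,
                 length_mm = sqrt(sum(((p1 - p0) * spacing)^2)),
                 plane = plane),
            class = "axis_line2d")
}

#' @export
print.axis_line2d <- function(x, ...) {
  cat(sprintf("<axis_line2d> (%.2f, %.2f) -> (%.2f, %.2f), %.2f mm%s\n",
              x$p0[1], x$p0[2], x$p1[1], x$p1[2], x$length_mm,
              if (!is.null(x$plane)) paste0(" [", x$plane, "]") else ""))
  invisible(x)
}

axis_midpoint <- function(axis) (axis$p0 + axis$p1) / 2

## angle of the axis direction in degrees, mapped to [0, 180)
axis_angle_deg <- function(axis) {
  v <- axis$p1 - axis$p0
  (atan2(v[2], v[1]) * 180 / pi) %% 180
}

#' Boundary pixels of a 2D mask, contour-ordered
#'
#' A boundary pixel is a `TRUE` pixel 8-adjacent to a `FALSE` pixel or to the
#' image edge. Pixels are grouped into 8-connected contours and ordered by an
#' adjacency walk along each contour; the outermost contour (smallest
#' bounding-box minimum) comes first, so ring-shaped masks report the outer
#' contour before the inner one.
#'
#' @param mask2d Logical matrix, nonempty.
#' @return n x 2 integer matrix of `(row, col)` boundary pixels with
#'   attribute `contour` (integer contour id per row).
#' @export
boundary_points <- function(mask2d) {
  if (!any(mask2d)) stop("empty mask has no boundary", call. = FALSE)
  d <- dim(mask2d)
  padded <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask2d
  interior <- matrix(TRUE, d[1], d[2])
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    interior <- interior & padded[(2:(d[1] + 1L)) + dr, (2:(d[2] + 1L)) + dc]
  }
  border <- mask2d & !interior
  lab <- cc_label(border, 8L)
  k <- max(lab)
  # order contours: outermost (lexicographically smallest min pixel) first
  comp_key <- t(vapply(seq_len(k), function(i) {
    co <- which_coords(lab == i)
    c(min(co[, 1]), min(co[, 2]))
  }, numeric(2)))
  ord <- order(comp_key[, 1], comp_key[, 2])
  out <- NULL; cid <- integer(0)
  for (ci in seq_along(ord)) {
    co <- which_coords(lab == ord[ci])
    out <- rbind(out, contour_walk(co))
    cid <- c(cid, rep(ci, nrow(co)))
  }
  dimnames(out) <- NULL
  attr(out, "contour") <- cid
  out
}

## Order the pixels of one thin closed contour by a greedy adjacency walk.
contour_walk <- function(co) {
  n <- nrow(co)
  if (n <= 2L) return(co)
  start <- order(co[, 1], co[, 2])[1]
  visited <- logical(n)
  path <- integer(n)
  cur <- start
  for (step in seq_len(n)) {
    path[step] <- cur
    visited[cur] <- TRUE
    dr <- abs(co[, 1] - co[cur, 1]); dc <- abs(co[, 2] - co[cur, 2])
    nb <- which(!visited & dr <= 1L & dc <= 1L)
    if (length(nb) == 0L) {
      nb <- which(!visited)
      if (length(nb) == 0L) break
      # spur or 8-gap: jump to the nearest unvisited pixel
      nb <- nb[which.min((co[nb, 1] - co[cur, 1])^2 + (co[nb, 2] - co[cur, 2])^2)]
    } else {
      # prefer 4-neighbours for a tight walk
      pri <- dr[nb] + dc[nb]
      nb <- nb[order(pri, co[nb, 1], co[nb, 2])][1]
    }
    cur <- nb
  }
  co[path[path > 0L], , drop = FALSE]
}

#' True longest axis of a 2D mask
#'
#' The boundary-pixel pair at maximum Euclidean (mm) distance — equivalent to
#' brute force over all boundary pairs.
#'
#' @param mask2d Logical matrix, nonempty.
#' @param spacing In-plane spacing (mm).
#' @return An [axis_line()].
#' @export
true_longest_axis <- function(mask2d, spacing = c(1, 1)) {
  bp <- boundary_points(mask2d)
  if (nrow(bp) == 1L) return(axis_line(bp[1, ], bp[1, ], spacing))
  x <- bp[, 1] * spacing[1]; y <- bp[, 2] * spacing[2]
  d2 <- outer(x, x, `-`)^2 + outer(y, y, `-`)^2
  idx <- arrayInd(which.max(d2), dim(d2))
  axis_line(bp[idx[1], ], bp[idx[2], ], spacing)
}

#' Fit an ellipse to a 2D mask by PCA
#'
#' Centre = pixel centroid; orientation and axis lengths come from the
#' eigendecomposition of the pixel coordinate covariance. For an exactly
#' elliptical pixel distribution the half-lengths `2 * sqrt(eigenvalue)`
#' recover the semi-axes.
#'
#' @param mask2d Logical matrix with at least 3 non-collinear pixels.
#' @param spacing In-plane spacing (mm).
#' @return An `ellipse2d`: `center` (row, col, pixels), `major_len`,
#'   `minor_len` (full lengths, mm), `orientation_deg` in `[0, 180)` measured
#'   from the +row axis.
#' @export
fit_ellipse_pca <- function(mask2d, spacing = c(1, 1)) {
  co <- which_coords(mask2d)
  if (nrow(co) < 3L) stop("mask too small for ellipse fit (< 3 pixels)", call. = FALSE)
  mm <- sweep(co, 2, spacing, `*`)
  ctr <- colMeans(mm)
  cv <- stats::cov(mm)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] <= 1e-9 * max(eg$values[1], 1))
    stop("degenerate mask: pixels are collinear", call. = FALSE)
  v <- eg$vectors[, 1]
  structure(list(center = ctr / spacing,
                 major_len = 4 * sqrt(eg$values[1]),
                 minor_len = 4 * sqrt(eg$values[2]),
                 orientation_deg = (atan2(v[2], v[1]) * 180 / pi) %% 180),
            class = "ellipse2d")
}

#' @export
print.ellipse2d <- function(x, ...) {
  cat(sprintf("<ellipse2d> center (%.1f, %.1f), %.1f x %.1f mm @ %.1f deg\n",
              x$center[1], x$center[2], x$major_len, x$minor_len,
              x$orientation_deg))
  invisible(x)
}

## Longest boundary-to-boundary chord of mask2d in the fixed direction
## `theta_deg`: the boundary-pixel pair at maximum Euclidean distance among
## pairs whose perpendicular offsets differ by at most `slab_tol` pixels
## (i.e. the pair is parallel to the direction up to the lattice
## resolution). Returns NULL when no such pair exists.
longest_chord <- function(mask2d, theta_deg, spacing = c(1, 1),
                          slab_tol = 0.5) {
  bp <- boundary_points(mask2d)
  mm <- sweep(unclass(bp)[, 1:2, drop = FALSE], 2, spacing, `*`)
  th <- theta_deg * pi / 180
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  t <- as.numeric(mm %*% u); s <- as.numeric(mm %*% v)
  d2 <- outer(mm[, 1], mm[, 1], `-`)^2 + outer(mm[, 2], mm[, 2], `-`)^2
  d2[abs(outer(s, s, `-`)) > slab_tol * max(spacing)] <- -Inf
  best <- arrayInd(which.max(d2), dim(d2))
  if (!is.finite(d2[best]) || d2[best] <= 0) return(NULL)
  # orient p0 -> p1 along +u
  ij <- if (t[best[1]] >= t[best[2]]) c(best[2], best[1]) else best
  axis_line(bp[ij[1], ], bp[ij[2], ], spacing)
}

#' Medially positioned long axis
#'
#' The longest chord of the mask parallel to the PCA ellipse's major axis.
#' Compared with the true longest axis this tends to cross the lesion centre,
#' where an intensity-driven engine can exploit symmetry.
#'
#' @param mask2d Logical matrix, nonempty.
#' @param ellipse Optional precomputed [fit_ellipse_pca()] result.
#' @param spacing In-plane spacing (mm).
#' @return An [axis_line()]. Falls back to [true_longest_axis()] with a
#'   warning when no chord exists at the ellipse orientation (e.g. sub-pixel
#'   masks).
#' @export
medial_long_axis <- function(mask2d, ellipse = NULL, spacing = c(1, 1)) {
  ell <- ellipse %||% tryCatch(fit_ellipse_pca(mask2d, spacing),
                               error = function(e) NULL)
  ch <- if (is.null(ell)) NULL else
    longest_chord(mask2d, ell$orientation_deg, spacing)
  if (is.null(ch)) {
    warning("no chord at ellipse orientation; falling back to true longest axis")
    return(true_longest_axis(mask2d, spacing))
  }
  ch
}

#' Short axis: longest chord perpendicular to the long axis
#'
#' Endpoints are boundary lattice pixels, so perpendicularity holds up to
#' the lattice resolution: the endpoints' offsets along the long-axis
#' direction differ by at most half a pixel, i.e. the deviation angle is
#' `atan(0.5 / length)` — well under a degree for typical axis lengths.
#'
#' @param mask2d Logical matrix, nonempty.
#' @param long_axis An [axis_line()] with positive length.
#' @param spacing In-plane spacing (mm).
#' @return An [axis_line()]; a zero-length axis (with a warning) when the
#'   mask admits no perpendicular chord.
#' @export
short_axis <- function(mask2d, long_axis, spacing = c(1, 1)) {
  if (long_axis$length_mm <= 0)
    stop("long axis has zero length", call. = FALSE)
  theta <- (axis_angle_deg(long_axis) + 90) %% 180
  ch <- longest_chord(mask2d, theta, spacing)
  if (is.null(ch)) {
    warning("mask admits no perpendicular chord; returning zero-length axis")
    m <- axis_midpoint(long_axis)
    return(axis_line(m, m, spacing))
  }
  ch
}

#' Angularly spaced boundary candidate points for the statistical axis search
#'
#' For each endpoint of the medial axis, `N + 1` boundary points are selected,
#' centred (index `r = N/2`, 0-based) on the endpoint itself, with neighbours
#' at successive multiples of `spacing_deg` of polar angle about the ellipse
#' centre. If the boundary cannot supply distinct points at that spacing, `N`
#' is reduced symmetrically with a warning.
#'
#' @param mask2d Logical matrix, nonempty.
#' @param medial The medial long axis ([medial_long_axis()]).
#' @param params An [axis_score_params()].
#' @param ellipse Optional precomputed ellipse (for its centre).
#' @return A `candidate_set`: `side0`, `side1` ((N+1) x 2 matrices of
#'   boundary points ordered by angle), `r` (centre index, 0-based), `N`.
#' @export
candidate_points <- function(mask2d, medial, params = axis_score_params(),
                             ellipse = NULL) {
  ell <- ellipse %||% tryCatch(fit_ellipse_pca(mask2d), error = function(e) NULL)
  ctr <- if (is.null(ell)) axis_midpoint(medial) else ell$center
  bp <- boundary_points(mask2d)
  ang <- atan2(bp[, 2] - ctr[2], bp[, 1] - ctr[1])   # radians, (-pi, pi]
  pick_side <- function(endpoint, r, spacing_rad) {
    th0 <- atan2(endpoint[2] - ctr[2], endpoint[1] - ctr[1])
    idx <- integer(2L * r + 1L)
    used <- logical(nrow(bp))
    # centre index first (the endpoint itself, snapped to the boundary),
    # then outwards, taking the nearest *unused* pixel per target angle so
    # that sub-pixel angular spacing still yields distinct candidates
    ks <- order(abs(-r:r), -r:r)
    for (pos in ks) {
      k <- (-r:r)[pos]
      if (k == 0L) {
        j <- which.min(ifelse(used, Inf,
                              (bp[, 1] - endpoint[1])^2 + (bp[, 2] - endpoint[2])^2))
      } else {
        target <- th0 + k * spacing_rad
        dd <- abs(((ang - target + pi) %% (2 * pi)) - pi)
        j <- which.min(ifelse(used, Inf, dd))
      }
      idx[pos] <- j
      used[j] <- TRUE
    }
    idx
  }
  r <- as.integer(params$N / 2)
  if (nrow(bp) < 2L * r + 1L) {
    r <- max(0L, as.integer((nrow(bp) - 1L) / 2L))
    warning(sprintf("boundary too small for N = %d candidates; reduced to N = %d",
                    params$N, 2L * r))
  }
  spacing_rad <- params$spacing_deg * pi / 180
  i0 <- pick_side(medial$p0, r, spacing_rad)
  i1 <- pick_side(medial$p1, r, spacing_rad)
  structure(list(side0 = bp[i0, , drop = FALSE],
                 side1 = bp[i1, , drop = FALSE],
                 r = r, N = 2L * r),
            class = "candidate_set")
}
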