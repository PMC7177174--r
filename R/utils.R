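## Small numeric helpers shared across modules.

## Points along the segment p0 -> p1 at roughly `step` pixel spacing,
## endpoints included. Returns an n x 2 matrix.
segment_points <- function(p0, p1, step = 0.25) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len / step) + 1L)
  t <- seq(0, 1, length.out = n)
  cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
}

## Bilinear interpolation of a 2D matrix at continuous (row, col) points.
## Points are clamped to the valid domain.
bilinear_sample <- function(img, pts) {
  d <- dim(img)
  r <- pmin(pmax(pts[, 1], 1), d[1])
  c <- pmin(pmax(pts[, 2], 1), d[2])
  r0 <- pmin(floor(r), d[1] - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(c), d[2] - 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1L, c0)
  i01 <- cbind(r0, c0 + 1L); i11 <- cbind(r0 + 1L, c0 + 1L)
  img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
}

## Integer pixels covered by the segment p0 -> p1 (dense sampling + unique).
rasterize_segment <- function(p0, p1, dim2) {
  pts <- round(segment_points(p0, p1, step = 0.4))
  pts[, 1] <- pmin(pmax(pts[, 1], 1L), dim2[1])
  pts[, 2] <- pmin(pmax(pts[, 2], 1L), dim2[2])
  unique(pts)
}

## Logical matrix TRUE within `radius` (pixels) of `center`, optionally only
## within the annulus [inner, radius].
disc_mask <- function(dim2, center, radius, inner = 0) {
  dr <- (seq_len(dim2[1]) - center[1])^2
  dc <- (seq_len(dim2[2]) - center[2])^2
  d2 <- outer(dr, dc, `+`)
  m <- d2 <= radius^2
  if (inner > 0) m <- m & d2 >= inner^2
  m
}

## Euclidean distance from each point in `pts` (n x 2) to the nearest point
## in `ref` (m x 2). Returns length-n vector. Both small sets; direct method.
min_dist_to_set <- function(pts, ref) {
  if (is.null(dim(pts))) pts <- rbind(pts)
  if (is.null(dim(ref))) ref <- rbind(ref)
  if (nrow(ref) == 0L) return(rep(Inf, nrow(pts)))
  d2 <- outer(pts[, 1], ref[, 1], `-`)^2 + outer(pts[, 2], ref[, 2], `-`)^2
  sqrt(apply(d2, 1, min))
}

## Coordinates (n x 2 or n x 3) of TRUE entries of a logical array.
which_coords <- function(mask) {
  arrayInd(which(mask), dim(mask))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
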