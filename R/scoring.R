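#' @title Statistical long-axis scoring
#'
#' @description The statistical drawing strategy searches axes drawn between
#' angularly spaced boundary candidate points and scores each one as
#'
#' \deqn{Score = \alpha (1 - D_{KL}) + \beta \cdot Length + \gamma \cdot Centrality}
#'
#' where `Length` is the axis length relative to the true longest axis,
#' `Centrality = 0.1 + 0.9 C / (2r)` with `C = |i - r| + |j - r|` (halved when
#' `i` and `j` lie on the same side of the centre index `r`), and
#' \eqn{D_{KL}(P \| Q) = \sum_x P(x) \log(P(x)/Q(x))} compares the
#' Parzen-window intensity density of all lesion pixels (`P`) with that of the
#' pixels sampled under the candidate axis (`Q`). Since an intensity-driven
#' segmentation engine samples statistics under the drag, a low divergence
#' means the drag "typifies" the lesion.
#' @name axis_scoring
NULL

#' Parameters of the statistical axis score
#'
#' @param alpha,beta,gamma Non-negative weights of the divergence, length and
#'   centrality terms. Defaults 0.5 / 0.3 / 0.2.
#' @param N Candidate count per endpoint side; even, `>= 2`. Each side gets
#'   `N + 1` boundary points indexed `0..N` with centre `r = N/2`.
#' @param spacing_deg Polar-angle spacing between neighbouring candidates.
#' @param sweep_arc_mm Half-length of the boundary sweep path of the
#'   sweeping strategy, mm each direction.
#' @param bandwidth Parzen kernel width in intensity units; `NULL` = 2% of
#'   the plane's intensity range.
#' @param n_bins Intensity grid resolution for the Parzen densities.
#' @param kl_floor Smoothing added to `Q` bins before the log.
#' @param invert_centrality If `TRUE`, use `0.1 + 0.9 (1 - C/(2r))` so that
#'   candidates *nearer* the medial endpoints score higher (the formula as
#'   printed rewards peripheral candidates; see the methods vignette).
#' @return An `axis_score_params` list.
#' @export
axis_score_params <- function(alpha = 0.5, beta = 0.3, gamma = 0.2,
                              N = 8L, spacing_deg = 3, sweep_arc_mm = 10,
                              bandwidth = NULL, n_bins = 256L,
                              kl_floor = 1e-8, invert_centrality = FALSE) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, N >= 2L, N %% 2L == 0L,
            spacing_deg > 0, sweep_arc_mm > 0, n_bins >= 8L, kl_floor > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, N = as.integer(N),
                 spacing_deg = spacing_deg, sweep_arc_mm = sweep_arc_mm,
                 bandwidth = bandwidth, n_bins = as.integer(n_bins),
                 kl_floor = kl_floor, invert_centrality = invert_centrality),
            class = "axis_score_params")
}

#' Parzen-window (Gaussian kernel) density estimate
#'
#' @param samples Numeric vector of intensities, nonempty.
#' @param bandwidth Gaussian kernel standard deviation, `> 0`.
#' @param grid Ordered vector of intensity bin centres.
#' @return An `intensity_pdf`: `grid`, `density` (integrates to 1 over the
#'   grid), `bandwidth`.
#' @export
parzen_pdf <- function(samples, bandwidth, grid) {
  if (length(samples) == 0L) stop("no intensity samples", call. = FALSE)
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  dens <- rowMeans(outer(grid, samples, function(x, s)
    stats::dnorm(x, mean = s, sd = bandwidth)))
  dx <- if (length(grid) > 1L) diff(grid)[1] else 1
  total <- sum(dens) * dx
  if (total <= 0) dens <- rep(1 / (length(grid) * dx), length(grid))
  else dens <- dens / total
  structure(list(grid = grid, density = dens, bandwidth = bandwidth),
            class = "intensity_pdf")
}

#' Kullback-Leibler divergence between two gridded densities
#'
#' \eqn{D_{KL}(P \| Q) = \sum_x P(x) \log(P(x)/Q(x))} over the shared grid
#' (probability masses per bin), with `kl_floor` added to `Q` before the log
#' so that intensity modes missed by `Q` do not produce infinities.
#'
#' @param P,Q `intensity_pdf` objects on the same grid.
#' @param kl_floor Smoothing epsilon for `Q`.
#' @return Non-negative divergence in nats (0 iff `P == Q`, up to floor
#'   effects).
#' @export
kl_divergence <- function(P, Q, kl_floor = 1e-8) {
  if (!isTRUE(all.equal(P$grid, Q$grid)))
    stop("P and Q must share the same intensity grid", call. = FALSE)
  dx <- if (length(P$grid) > 1L) diff(P$grid)[1] else 1
  p <- P$density * dx
  q <- Q$density * dx
  p <- p / sum(p)
  q <- q / sum(q) + kl_floor
  nz <- p > 0
  max(0, sum(p[nz] * log(p[nz] / q[nz])))
}

#' Centrality term of the axis score
#'
#' `Centrality = 0.1 + 0.9 * C / (2r)` with `C = |i - r| + |j - r|`, halved
#' when `i` and `j` both lie on the same side of the centre index `r` to
#' favour axes that cross the centre. Indices are 0-based positions in the
#' candidate sets (`0 <= i, j <= 2r`).
#'
#' @param i,j Candidate indices on each side.
#' @param r Centre index (`N/2`), `> 0`.
#' @param same_side `TRUE` when `i` and `j` are on the same side of `r`;
#'   derived from `i`, `j` when `NULL`.
#' @param invert Use the inverted (centre-rewarding) form.
#' @return Value in `[0.1, 1.0]`.
#' @export
centrality_term <- function(i, j, r, same_side = NULL, invert = FALSE) {
  if (r <= 0) stop("r must be positive", call. = FALSE)
  if (any(i < 0 | i > 2 * r | j < 0 | j > 2 * r))
    stop("candidate indices must lie in [0, 2r]", call. = FALSE)
  if (is.null(same_side)) same_side <- (i - r) * (j - r) > 0
  C <- abs(i - r) + abs(j - r)
  C <- ifelse(same_side, C / 2, C)
  frac <- C / (2 * r)
  if (invert) 0.1 + 0.9 * (1 - frac) else 0.1 + 0.9 * frac
}

## Intensities under an axis: bilinear samples at 0.25-px steps.
axis_samples <- function(image2d, axis) {
  bilinear_sample(image2d, segment_points(axis$p0, axis$p1, step = 0.25))
}

## Shared Parzen setup for a plane: grid + bandwidth from the image range.
plane_pdf_setup <- function(image2d, params) {
  rng <- range(image2d)
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  bw <- params$bandwidth %||% (0.02 * diff(rng))
  list(grid = seq(rng[1], rng[2], length.out = params$n_bins), bandwidth = bw)
}

#' Score one candidate axis
#'
#' @param axis Candidate [axis_line()] with endpoints taken from a candidate
#'   set at indices `i`, `j`.
#' @param i,j 0-based candidate indices (see [centrality_term()]).
#' @param mask2d Ground-truth 2D mask (defines `P`).
#' @param image2d Intensity plane (defines the samples for `Q`).
#' @param truelong_len Length of the true longest axis, mm.
#' @param params [axis_score_params()].
#' @param P Optional precomputed lesion `intensity_pdf` (recomputed when
#'   `NULL`).
#' @param setup Optional precomputed grid/bandwidth from `plane_pdf_setup`.
#' @return Scalar score. The divergence is clamped to `[0, 1]` before use so
#'   `1 - D_KL` stays a bounded reward.
#' @export
score_axis <- function(axis, i, j, mask2d, image2d, truelong_len,
                       params = axis_score_params(), P = NULL, setup = NULL) {
  if (axis$length_mm <= 0) stop("zero-length axis cannot be scored", call. = FALSE)
  su <- setup %||% plane_pdf_setup(image2d, params)
  if (is.null(P)) P <- parzen_pdf(image2d[mask2d], su$bandwidth, su$grid)
  Q <- parzen_pdf(axis_samples(image2d, axis), su$bandwidth, su$grid)
  dkl <- clamp(kl_divergence(P, Q, params$kl_floor), 0, 1)
  r <- as.integer(params$N / 2)
  params$alpha * (1 - dkl) +
    params$beta * (axis$length_mm / truelong_len) +
    params$gamma * centrality_term(i, j, r, invert = params$invert_centrality)
}

#' Statistical axis search over all candidate pairs
#'
#' Evaluates [score_axis()] for every `(i, j)` pair of the candidate set and
#' returns the argmax (ties broken by lowest `(i, j)` lexicographically).
#'
#' @param mask2d Ground-truth 2D mask, nonempty.
#' @param image2d Intensity plane.
#' @param params [axis_score_params()].
#' @param spacing In-plane spacing (mm).
#' @return The winning [axis_line()], with attributes `i`, `j`, `score`.
#' @export
statistical_axis_search <- function(mask2d, image2d,
                                    params = axis_score_params(),
                                    spacing = c(1, 1)) {
  medial <- medial_long_axis(mask2d, spacing = spacing)
  cs <- candidate_points(mask2d, medial, params)
  tl <- true_longest_axis(mask2d, spacing)$length_mm
  if (tl <= 0) return(medial)
  su <- plane_pdf_setup(image2d, params)
  P <- parzen_pdf(image2d[mask2d], su$bandwidth, su$grid)
  r <- cs$r
  prm <- params; prm$N <- 2L * r   # honour any symmetric reduction
  best <- NULL
  for (i in 0:(2L * r)) {
    for (j in 0:(2L * r)) {
      ax <- axis_line(cs$side0[i + 1L, ], cs$side1[j + 1L, ], spacing)
      if (ax$length_mm <= 0) next
      sc <- score_axis(ax, i, j, mask2d, image2d, tl, prm, P = P, setup = su)
      if (is.null(best) || sc > best$score + 1e-12) {
        best <- list(axis = ax, i = i, j = j, score = sc)
      }
    }
  }
  if (is.null(best)) return(medial)
  out <- best$axis
  attr(out, "i") <- best$i; attr(out, "j") <- best$j
  attr(out, "score") <- best$score
  out
}

#' Sweep one axis endpoint along the boundary
#'
#' Holds `p0` fixed and slides `p1` along the mask boundary within an arc
#' length of `sweep_arc_mm` in each direction (one boundary pixel per step,
#' start position included). Each position triggers the engine's interactive
#' 2D segmentation, which is scored by Dice overlap against the ground-truth
#' cross-section; the best position wins, so the result never scores below
#' the starting axis.
#'
#' @param start Starting [axis_line()] whose `p1` lies on (or near) the
#'   boundary.
#' @param mask2d Ground-truth 2D mask.
#' @param image2d Intensity plane.
#' @param engine A segmentation engine (see [parzen_engine()]).
#' @param gt2d Ground truth used for scoring (defaults to `mask2d`).
#' @param params [axis_score_params()] (for `sweep_arc_mm`).
#' @param spacing In-plane spacing (mm).
#' @return The best [axis_line()], with attribute `dsc` (the winning 2D
#'   Dice).
#' @export
sweep_axis <- function(start, mask2d, image2d, engine, gt2d = mask2d,
                       params = axis_score_params(), spacing = c(1, 1)) {
  bp <- boundary_points(mask2d)
  cid <- attr(bp, "contour")
  near <- which.min((bp[, 1] - start$p1[1])^2 + (bp[, 2] - start$p1[2])^2)
  on_contour <- which(cid == cid[near])
  ring <- bp[on_contour, , drop = FALSE]
  pos <- which(on_contour == near)
  n <- nrow(ring)
  # arc length along the contour walk, mm
  step_mm <- sqrt(sum((diff(rbind(ring, ring[1, ])) %*% diag(spacing))^2) / n)
  k <- min(floor(params$sweep_arc_mm / max(step_mm, 1e-6)), floor((n - 1) / 2))
  offsets <- if (k >= 1) (-k):k else 0L
  cand_idx <- unique(((pos - 1 + offsets) %% n) + 1)
  best <- NULL
  for (ci in cand_idx) {
    ax <- axis_line(start$p0, ring[ci, ], spacing)
    if (ax$length_mm <= 0) next
    seg <- tryCatch(
      engine$segment_2d(image2d,
                        interaction_input(axes = list(ax)), spacing = spacing),
      error = function(e) NULL)
    if (is.null(seg)) { warning("sweep position skipped: engine failure"); next }
    sc <- dsc(seg, gt2d)
    is_start <- ci == pos
    if (is.null(best) || sc > best$dsc + 1e-12 ||
        (is_start && sc >= best$dsc - 1e-12)) {
      # start position wins ties so the sweep can only improve on it
      best <- list(axis = ax, dsc = sc)
    }
  }
  if (is.null(best)) stop("sweep failed at every position", call. = FALSE)
  out <- best$axis
  attr(out, "dsc") <- best$dsc
  out
}
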