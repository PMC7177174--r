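#' @title Reference interactive segmentation engine
#'
#' @description A pluggable engine turns user interactions (axes, dropped
#' boundary points, replacement masks) into segmentations through three
#' stages that mirror an interactive MPR workflow: a real-time 2D
#' segmentation on the drawn plane, a 3-plane "scout" segmentation that
#' re-estimates its intensity model from the 2D result, and a final 3D
#' segmentation seeded by the scout planes.
#'
#' The reference engine (`"parzen_rg"`) is a probabilistic region grower:
#' (1) a Parzen foreground density is estimated from intensities sampled
#' under the user's lines; (2) a background density from a ring of pixels at
#' the boundary of a region of interest (ROI) centred at the long-axis
#' midpoint; (3) each ROI pixel gets a posterior under equal priors;
#' (4) pixels above `posterior_threshold` are kept; (5) the connected
#' component containing the axis is retained; (6) holes are filled; and
#' (7) dropped points are enforced by local correction (a bridge is grown to
#' an excluded drop; a notch is carved past an over-included one) until each
#' drop lies within `drop_tolerance_px` of the segmentation boundary.
#' All stages are deterministic given their inputs.
#' @name seg_engine
NULL

#' Engine configuration
#'
#' @param roi_radius_factor ROI radius as a multiple of half the long-axis
#'   length (and of the per-plane half-extents for the 3D ellipsoid).
#' @param posterior_threshold Foreground posterior cut in (0, 1).
#' @param drop_tolerance_px Maximum distance from a dropped point to the
#'   resulting 2D boundary.
#' @param bandwidth Parzen kernel width; `NULL` = 2% of the plane range.
#' @param n_bins Intensity grid size for the Parzen densities.
#' @param kl_floor Shared smoothing epsilon.
#' @return An `engine_config` list.
#' @export
engine_config <- function(roi_radius_factor = 1.5, posterior_threshold = 0.5,
                          drop_tolerance_px = 1.5, bandwidth = NULL,
                          n_bins = 256L, kl_floor = 1e-8) {
  stopifnot(roi_radius_factor > 0, posterior_threshold > 0,
            posterior_threshold < 1, drop_tolerance_px > 0)
  structure(list(roi_radius_factor = roi_radius_factor,
                 posterior_threshold = posterior_threshold,
                 drop_tolerance_px = drop_tolerance_px,
                 bandwidth = bandwidth, n_bins = as.integer(n_bins),
                 kl_floor = kl_floor),
            class = "engine_config")
}

#' Bundle user interactions for one plane
#'
#' @param axes List of [axis_line()] drags (the first is the long axis).
#' @param drops `n x 2` matrix of dropped boundary points (rows `(row, col)`),
#'   or `NULL`.
#' @param replace_mask Optional replacement 2D mask (edit-to-perfection).
#' @return An `interaction_input` list.
#' @export
interaction_input <- function(axes = list(), drops = NULL, replace_mask = NULL) {
  if (!is.null(drops)) drops <- rbind(drops)
  structure(list(axes = axes, drops = drops, replace_mask = replace_mask),
            class = "interaction_input")
}

## ---------------------------------------------------------------------------
## engine registry (entry-point style plug-in mechanism)

.engine_registry <- new.env(parent = emptyenv())

#' Register a segmentation engine constructor
#'
#' Third-party engines plug in by name. A constructor takes an
#' [engine_config()] and must return a list with functions `segment_2d`,
#' `segment_scout`, `segment_3d` (and optionally `resegment_plane`)
#' honouring the stage contracts of the reference engine.
#'
#' @param name Engine name used in configs.
#' @param constructor `function(config) -> engine`.
#' @export
register_engine <- function(name, constructor) {
  assign(name, constructor, envir = .engine_registry)
  invisible(name)
}

#' Instantiate a segmentation engine by name
#'
#' @param name Registered engine name; `"parzen_rg"` is the reference engine.
#' @param config An [engine_config()].
#' @return A `seg_engine` object.
#' @export
make_engine <- function(name = "parzen_rg", config = engine_config()) {
  if (!exists(name, envir = .engine_registry))
    stop(sprintf("unknown engine '%s'; registered: %s", name,
                 paste(ls(.engine_registry), collapse = ", ")), call. = FALSE)
  eng <- get(name, envir = .engine_registry)(config)
  eng$name <- name
  class(eng) <- "seg_engine"
  eng
}

#' @export
print.seg_engine <- function(x, ...) {
  cat(sprintf("<seg_engine> %s\n", x$name)); invisible(x)
}

## ---------------------------------------------------------------------------
## segmentation state

#' Construct a segmentation state
#'
#' Tracks the stage progression `2D -> scout -> 3D`, the per-plane 2D masks,
#' the plane indices, the 3D mask (stage `"3d"` only) and a snapshot of the
#' interactions that produced them.
#'
#' @param stage `"2d"`, `"scout"` or `"3d"`.
#' @param plane_masks Named list (`axial`, `coronal`, `sagittal`) of 2D masks.
#' @param plane_index Named integer vector of fixed plane positions.
#' @param mid3 3D coordinate of the long-axis midpoint.
#' @param volume_mask Logical 3D array (stage `"3d"`).
#' @param interaction Named list of per-plane [interaction_input()]s.
#' @return A `seg_state`.
#' @export
seg_state <- function(stage, plane_masks = list(), plane_index = c(),
                      mid3 = NULL, volume_mask = NULL, interaction = list()) {
  stopifnot(stage %in% c("2d", "scout", "3d"))
  structure(list(stage = stage, plane_masks = plane_masks,
                 plane_index = plane_index, mid3 = mid3,
                 volume_mask = volume_mask, interaction = interaction),
            class = "seg_state")
}

#' @export
print.seg_state <- function(x, ...) {
  cat(sprintf("<seg_state> stage %s, planes: %s%s\n", x$stage,
              paste(names(x$plane_masks), collapse = ", "),
              if (!is.null(x$volume_mask))
                sprintf(", 3D mask %d voxels", sum(x$volume_mask)) else ""))
  invisible(x)
}

## ---------------------------------------------------------------------------
## reference engine internals

## Density lookup: binned Parzen estimate (grid histogram convolved with the
## Gaussian kernel — equivalent to the exact estimator at grid resolution,
## the kernel spanning several bins), interpolated at the query intensities.
pdf_lookup <- function(samples, grid, bandwidth, at) {
  n <- length(grid)
  dx <- if (n > 1L) grid[2] - grid[1] else 1
  bins <- clamp(findInterval(samples, grid - dx / 2), 1L, n)
  counts <- tabulate(bins, nbins = n)
  m <- max(1L, ceiling(4 * bandwidth / dx))
  kern <- stats::dnorm(seq(-m, m) * dx, sd = bandwidth)
  dens <- stats::filter(c(rep(0, m), counts, rep(0, m)), kern,
                        method = "convolution", sides = 2)
  dens <- as.numeric(dens)[(m + 1):(m + n)]
  total <- sum(dens) * dx
  dens <- if (total > 0) dens / total else rep(1 / (n * dx), n)
  stats::approx(grid, dens, xout = clamp(at, grid[1], grid[n]), rule = 2)$y
}

## Intensity samples under an axis for the foreground model, excluding a
## small margin at each endpoint: endpoints sit on the structure boundary,
## where partial-volume mixing with background would broaden the model.
axis_fg_samples <- function(img2, axis, margin_px = 1) {
  len <- sqrt(sum((axis$p1 - axis$p0)^2))
  m <- min(margin_px, 0.2 * len) / max(len, 1e-9)
  u <- axis$p1 - axis$p0
  bilinear_sample(img2, segment_points(axis$p0 + m * u, axis$p1 - m * u,
                                       step = 0.25))
}

## Robust foreground model: keep the central quantile band of the samples.
## Samples taken near the structure boundary (axis endpoints, the rim of a
## learned 2D mask) are partial-volume mixtures with background; trimming
## the tails keeps the model from bleeding across the boundary. Interior
## modes (e.g. a dark necrotic core) survive the 10% trim, and fully
## enclosed regions lost to it are recovered by hole filling.
robust_band <- function(samples, lo = 0.1, hi = 0.9) {
  if (length(samples) < 10L) return(samples)
  q <- stats::quantile(samples, c(lo, hi), names = FALSE, type = 7)
  kept <- samples[samples >= q[1] & samples <= q[2]]
  if (length(kept) == 0L) samples else kept
}

## Core 2D probabilistic region growing shared by the 2D and scout stages.
## fg_samples: intensity samples of the foreground model; seeds: integer
## pixel matrix that must be contained; center/radius define the ROI disc.
parzen_core_2d <- function(img2, fg_samples, center, radius, seeds,
                           drops, cfg, spacing = c(1, 1)) {
  d <- dim(img2)
  radius <- max(radius, 2)
  if (!is.null(drops) && nrow(drops) > 0) {
    dd <- sqrt((drops[, 1] - center[1])^2 + (drops[, 2] - center[2])^2)
    radius <- max(radius, max(dd) + 3)
  }
  if (!is.null(drops) && nrow(drops) > 0) {
    # a dropped boundary point implies the tissue between the axis centre
    # and the drop belongs to the structure: fold it into the model
    fg_samples <- c(fg_samples, unlist(lapply(seq_len(nrow(drops)), function(b)
      bilinear_sample(img2, segment_points(center, drops[b, ], step = 0.5)))))
  }
  roi <- disc_mask(d, center, radius)
  ring <- disc_mask(d, center, radius + 2) & !roi
  if (!any(ring)) ring <- !roi
  if (!any(ring)) ring <- roi   # degenerate tiny image: flat posterior
  rng <- range(img2)
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  bw <- cfg$bandwidth %||% (0.02 * diff(rng))
  grid <- seq(rng[1], rng[2], length.out = cfg$n_bins)
  idx <- which(roi)
  vals <- img2[idx]
  pf <- pdf_lookup(robust_band(fg_samples), grid, bw, vals)
  pb <- pdf_lookup(img2[ring], grid, bw, vals)
  post <- pf / (pf + pb + 1e-300)
  sel <- array(FALSE, d)
  sel[idx[post > cfg$posterior_threshold]] <- TRUE
  seed_lin <- seeds[, 1] + (seeds[, 2] - 1L) * d[1]
  finalize <- function(sel) {
    sel[seeds] <- TRUE
    sel <- keep_components_with(sel, seed_lin, 8L)
    fill_holes(sel)
  }
  sel <- finalize(sel)
  violations <- integer(0)
  if (!is.null(drops) && nrow(drops) > 0) {
    for (pass in 1:3) {
      bnd <- if (any(sel)) boundary_points(sel) else cbind(numeric(0), numeric(0))
      dist <- min_dist_to_set(drops, bnd)
      bad <- which(dist > cfg$drop_tolerance_px)
      if (length(bad) == 0L) break
      for (b in bad) {
        p <- drops[b, ]
        pi <- clamp(round(p), 1, d)
        if (!sel[pi[1], pi[2]]) {
          # excluded drop: grow a bridge from the nearest mask pixel
          if (any(sel)) {
            sc <- which_coords(sel)
            nb <- sc[which.min((sc[, 1] - p[1])^2 + (sc[, 2] - p[2])^2), ]
            px <- rasterize_segment(nb, p, d)
            sel[px] <- TRUE
          }
          sel[pi[1], pi[2]] <- TRUE
        } else {
          # over-included drop: carve an open notch past the drop
          u <- p - center
          nu <- sqrt(sum(u^2))
          u <- if (nu < 1e-9) c(1, 0) else u / nu
          ray <- segment_points(p + 0.75 * u, p + (radius + 3) * u, step = 0.4)
          co <- which_coords(sel)
          keep <- min_dist_to_set(co, ray) > 1.2
          sel <- array(FALSE, d)
          sel[co[keep, , drop = FALSE]] <- TRUE
        }
      }
      sel <- finalize(sel)
    }
    bnd <- if (any(sel)) boundary_points(sel) else cbind(numeric(0), numeric(0))
    violations <- which(min_dist_to_set(drops, bnd) > cfg$drop_tolerance_px)
    if (length(violations) > 0L)
      warning(sprintf("%d drop constraint(s) unsatisfied (best effort)",
                      length(violations)))
  }
  attr(sel, "constraint_violations") <- violations
  attr(sel, "roi_radius") <- radius
  sel
}

## half-extents (px) of a 2D mask along its two in-plane axes
mask_half_extents <- function(mask2d) {
  if (!any(mask2d)) return(c(1, 1))
  co <- which_coords(mask2d)
  c(diff(range(co[, 1])) + 1, diff(range(co[, 2])) + 1) / 2
}

#' Reference Parzen region-growing engine
#'
#' @param config An [engine_config()].
#' @return A `seg_engine` with functions `segment_2d(image2d, interaction,
#'   spacing)`, `segment_scout(vol, state, mpr_interaction)`,
#'   `segment_3d(vol, state)` and `resegment_plane(vol, state, plane,
#'   interaction)`.
#' @export
parzen_engine <- function(config = engine_config()) {
  cfg <- config

  segment_2d <- function(image2d, interaction, spacing = c(1, 1)) {
    axes <- interaction$axes
    if (length(axes) == 0L)
      stop("segment_2d requires at least one axis", call. = FALSE)
    long <- axes[[1]]
    if (long$length_mm <= 0) stop("zero-length long axis", call. = FALSE)
    d <- dim(image2d)
    for (ax in axes) {
      if (any(ax$p0 < 0.5) || any(ax$p1 < 0.5) ||
          any(ax$p0 > d + 0.5) || any(ax$p1 > d + 0.5))
        stop("axis endpoint outside the image", call. = FALSE)
    }
    mid <- axis_midpoint(long)
    radius <- cfg$roi_radius_factor * (long$length_mm / 2) / mean(spacing)
    fg <- unlist(lapply(axes, function(a) axis_fg_samples(image2d, a)))
    seeds <- do.call(rbind, lapply(axes, function(a)
      rasterize_segment(a$p0, a$p1, d)))
    parzen_core_2d(image2d, fg, mid, radius, seeds,
                   interaction$drops, cfg, spacing)
  }

  scout_plane <- function(vol, state, plane, inter_p) {
    idx <- state$plane_index[[plane]]
    pl <- extract_plane(vol, plane, idx)
    img2 <- pl$data
    # intensity model re-estimated from the completed axial 2D result
    ax_img <- extract_plane(vol, "axial", state$plane_index[["axial"]])$data
    base_fg <- ax_img[state$plane_masks$axial]
    center <- plane_from3d(pl, state$mid3)
    if (length(inter_p$axes) > 0L) {
      long <- inter_p$axes[[1]]
      radius <- cfg$roi_radius_factor * (long$length_mm / 2) / mean(pl$spacing)
      center <- axis_midpoint(long)
      fg <- c(base_fg, unlist(lapply(inter_p$axes, function(a)
        axis_fg_samples(img2, a))))
      seeds <- do.call(rbind, lapply(inter_p$axes, function(a)
        rasterize_segment(a$p0, a$p1, dim(img2))))
    } else {
      he <- mask_half_extents(state$plane_masks$axial)
      radius <- cfg$roi_radius_factor * max(he)
      fg <- base_fg
      seeds <- rbind(clamp(round(center), 1, dim(img2)))
    }
    parzen_core_2d(img2, fg, center, radius, seeds, inter_p$drops, cfg,
                   pl$spacing)
  }

  segment_scout <- function(vol, state, mpr_interaction = list()) {
    if (is.null(state$plane_masks$axial))
      stop("scout stage requires a completed axial 2D mask", call. = FALSE)
    d <- dim(vol_data(vol))
    mid3 <- clamp(round(state$mid3), 1, d)
    state$plane_index <- c(axial = unname(state$plane_index[["axial"]]),
                           coronal = unname(mid3[2]), sagittal = unname(mid3[1]))
    for (plane in c("coronal", "sagittal")) {
      inter_p <- mpr_interaction[[plane]] %||% interaction_input()
      if (!is.null(inter_p$replace_mask)) {
        state$plane_masks[[plane]] <- inter_p$replace_mask
      } else {
        state$plane_masks[[plane]] <- scout_plane(vol, state, plane, inter_p)
      }
      state$interaction[[plane]] <- inter_p
    }
    state$stage <- "scout"
    state
  }

  segment_3d <- function(vol, state) {
    if (state$stage != "scout")
      stop("3D stage requires a completed scout", call. = FALSE)
    a <- vol_data(vol)
    d <- dim(a)
    mid3 <- clamp(round(state$mid3), 1, d)
    # embed the plane masks as 3D seeds
    seeds <- array(FALSE, d)
    pm <- state$plane_masks
    seeds[, , state$plane_index[["axial"]]] <- pm$axial
    seeds[, state$plane_index[["coronal"]], ] <-
      seeds[, state$plane_index[["coronal"]], ] | pm$coronal
    seeds[state$plane_index[["sagittal"]], , ] <-
      seeds[state$plane_index[["sagittal"]], , ] | pm$sagittal
    # ROI ellipsoid semi-axes from the per-plane mask extents
    he_ax <- mask_half_extents(pm$axial)      # x, y
    he_co <- mask_half_extents(pm$coronal)    # x, z
    he_sa <- mask_half_extents(pm$sagittal)   # y, z
    semi <- cfg$roi_radius_factor *
      pmax(c(he_ax[1], he_ax[2], he_co[2]),
           c(he_co[1], he_sa[1], he_sa[2]), 2)
    lo <- clamp(floor(mid3 - 1.25 * semi), 1, d)
    hi <- clamp(ceiling(mid3 + 1.25 * semi), 1, d)
    sub <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    ctr <- mid3 - lo + 1
    rho2 <- outer(outer(((seq_len(dim(sub)[1]) - ctr[1]) / semi[1])^2,
                        ((seq_len(dim(sub)[2]) - ctr[2]) / semi[2])^2, `+`),
                  ((seq_len(dim(sub)[3]) - ctr[3]) / semi[3])^2, `+`)
    roi <- rho2 <= 1
    shell <- rho2 > 1 & rho2 <= 1.44
    if (!any(shell)) shell <- !roi
    if (!any(shell)) shell <- roi
    rng <- range(sub)
    if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
    bw <- cfg$bandwidth %||% (0.02 * diff(rng))
    grid <- seq(rng[1], rng[2], length.out = cfg$n_bins)
    fg_samples <- a[seeds]
    idx <- which(roi)
    pf <- pdf_lookup(robust_band(fg_samples), grid, bw, sub[idx])
    pb <- pdf_lookup(sub[shell], grid, bw, sub[idx])
    post <- pf / (pf + pb + 1e-300)
    sel_sub <- array(FALSE, dim(sub))
    sel_sub[idx[post > cfg$posterior_threshold]] <- TRUE
    sub_seeds <- seeds[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sel_sub <- sel_sub | sub_seeds
    sel_sub <- keep_components_with(sel_sub, which(sub_seeds), 26L)
    sel_sub <- fill_holes(sel_sub)
    out <- array(FALSE, d)
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sel_sub
    state$volume_mask <- out
    state$stage <- "3d"
    state
  }

  list(config = cfg, segment_2d = segment_2d, segment_scout = segment_scout,
       segment_3d = segment_3d, resegment_plane = scout_plane)
}

register_engine("parzen_rg", parzen_engine)
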