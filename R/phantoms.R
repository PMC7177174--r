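#' @title Synthetic lesion phantoms
#'
#' @description Seeded generator of 3D image + ground-truth pairs with the
#' structure the simulation assumes: single or multiple lesions, convex
#' (ellipsoidal) or lobulated shapes, optional dark necrotic cores inside an
#' enhancing rim, intensity contrast over a noisy background, partial-volume
#' blur, and optional adjacency of two lesions that requires a separator
#' plane before enumeration. Truth masks are the pre-blur analytic shapes.
#' @name phantoms
NULL

#' Phantom specification
#'
#' @param volume_shape Integer length-3 lattice size.
#' @param spacing Voxel size, mm.
#' @param lesion_count Number of lesions.
#' @param shape_family `"ellipsoid"`, `"sphere"` (isotropic ellipsoid) or
#'   `"lobulated"` (star-shaped radial perturbation).
#' @param radius_range Min/max lesion radius, mm.
#' @param lobulation_amp Fractional radial perturbation amplitude in `[0, 1)`
#'   for lobulated shapes.
#' @param necrotic_core Add a concentric dark core (which still belongs to
#'   the target mask, as a non-enhancing core belongs to the gross tumour)?
#' @param core_fraction Core radius as a fraction of the lesion radius.
#' @param fg_mean,fg_sd Lesion (enhancing) intensity mean / texture sd.
#' @param bg_mean,bg_sd Background intensity mean / texture sd.
#' @param core_mean Core intensity (dark relative to the rim).
#' @param noise_sd Acquisition noise added after blurring.
#' @param smoothing_sigma Partial-volume Gaussian blur, mm.
#' @param adjacency Force exactly two lesions that touch (exercises
#'   separator handling).
#' @param seed Seed fixing every random choice.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(volume_shape = c(48L, 48L, 48L), spacing = c(1, 1, 1),
                         lesion_count = 1L,
                         shape_family = c("ellipsoid", "sphere", "lobulated"),
                         radius_range = c(8, 14), lobulation_amp = 0.25,
                         necrotic_core = FALSE, core_fraction = 0.5,
                         fg_mean = 100, fg_sd = 4, bg_mean = 20, bg_sd = 4,
                         core_mean = 45, noise_sd = 4, smoothing_sigma = 0.8,
                         adjacency = FALSE, seed = 1L) {
  shape_family <- match.arg(shape_family)
  if (adjacency) lesion_count <- 2L
  stopifnot(length(volume_shape) == 3L, all(volume_shape >= 8L),
            all(spacing > 0), lesion_count >= 1L,
            radius_range[1] > 0, radius_range[2] >= radius_range[1],
            lobulation_amp >= 0, lobulation_amp < 1,
            core_fraction > 0, core_fraction < 1,
            fg_mean != bg_mean)
  structure(list(volume_shape = as.integer(volume_shape), spacing = spacing,
                 lesion_count = as.integer(lesion_count),
                 shape_family = shape_family, radius_range = radius_range,
                 lobulation_amp = lobulation_amp,
                 necrotic_core = necrotic_core, core_fraction = core_fraction,
                 fg_mean = fg_mean, fg_sd = fg_sd, bg_mean = bg_mean,
                 bg_sd = bg_sd, core_mean = core_mean, noise_sd = noise_sd,
                 smoothing_sigma = smoothing_sigma, adjacency = adjacency,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Low-order spherical-harmonic-like radial perturbation; |value| <= 1.
## coef: length-5 seeded coefficients.
radial_perturbation <- function(theta, phi, coef) {
  basis <- cbind(cos(2 * theta),
                 sin(theta)^2 * cos(2 * phi),
                 sin(theta)^2 * sin(2 * phi),
                 sin(2 * theta) * cos(phi),
                 sin(theta)^3 * cos(3 * phi))
  as.numeric(basis %*% coef) / sum(abs(coef))
}

## Rasterize one lesion into a logical array over the full lattice.
## Returns list(mask, core) of logical arrays.
rasterize_lesion <- function(shape, dimv, spacing) {
  ctr <- shape$center
  rmax <- shape$r0 * (1 + shape$amp)
  lo <- clamp(floor(ctr - rmax / min(spacing) - 1), 1, dimv)
  hi <- clamp(ceiling(ctr + rmax / min(spacing) + 1), 1, dimv)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  dx <- (g$x - ctr[1]) * spacing[1]
  dy <- (g$y - ctr[2]) * spacing[2]
  dz <- (g$z - ctr[3]) * spacing[3]
  rr <- sqrt(dx^2 + dy^2 + dz^2)
  if (shape$family %in% c("ellipsoid", "sphere")) {
    q <- cbind(dx, dy, dz) %*% shape$rot
    inside <- (q[, 1] / shape$radii[1])^2 + (q[, 2] / shape$radii[2])^2 +
      (q[, 3] / shape$radii[3])^2 <= 1
    incore <- (q[, 1] / shape$radii[1])^2 + (q[, 2] / shape$radii[2])^2 +
      (q[, 3] / shape$radii[3])^2 <= shape$core_fraction^2
  } else {
    theta <- acos(ifelse(rr > 0, dz / rr, 1))
    phi <- atan2(dy, dx)
    rad <- shape$r0 * (1 + shape$amp *
                         radial_perturbation(theta, phi, shape$coef))
    inside <- rr <= rad
    incore <- rr <= rad * shape$core_fraction
  }
  mask <- array(FALSE, dimv); core <- array(FALSE, dimv)
  mask[cbind(g$x, g$y, g$z)[inside, , drop = FALSE]] <- TRUE
  core[cbind(g$x, g$y, g$z)[incore, , drop = FALSE]] <- TRUE
  list(mask = mask, core = core)
}

## Separable Gaussian blur with edge replication.
gauss_blur3 <- function(a, sigma_vox) {
  d <- dim(a)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    m <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-m:m, sd = s); w <- w / sum(w)
    out <- array(0, d)
    for (k in -m:m) {
      idx <- clamp(seq_len(d[axis]) + k, 1, d[axis])
      shifted <- switch(axis,
                        a[idx, , , drop = FALSE],
                        a[, idx, , drop = FALSE],
                        a[, , idx, drop = FALSE])
      out <- out + w[k + m + 1] * shifted
    }
    a <- out
  }
  a
}

#' Generate one synthetic phantom
#'
#' Lesions are placed without unintended overlap (unless adjacency is
#' requested, in which case exactly two lesions touch along a lattice axis
#' and a separator plane that splits them is returned). The image is built
#' from region means plus region texture noise, blurred for partial-volume
#' effect, with acquisition noise added last. The ground-truth label volume
#' holds the pre-blur analytic shapes (per-lesion ids 1..K; cores belong to
#' their lesion).
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom`: list with `volume` ([scalar_volume]), `labels`
#'   (integer array), `separator` (logical array or `NULL`), `lesions`
#'   (per-lesion analytic parameters), `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  dimv <- spec$volume_shape
  shapes <- list()
  if (spec$adjacency) {
    axis <- sample(1:3, 1)
    r1 <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
    r2 <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
    gap <- r1 + r2 - 1
    ctr1 <- vapply(1:3, function(i) {
      margin <- (if (i == axis) r1 else max(r1, r2)) + 2
      lo <- margin + 1
      hi <- dimv[i] - margin - (if (i == axis) gap + r2 - r1 else 0)
      if (hi <= lo) stop("volume too small for adjacent lesions", call. = FALSE)
      stats::runif(1, lo, hi)
    }, 0)
    ctr2 <- ctr1; ctr2[axis] <- ctr1[axis] + gap
    shapes <- list(
      list(family = "ellipsoid", center = ctr1, radii = rep(r1, 3),
           rot = diag(3), r0 = r1, amp = 0,
           core_fraction = if (spec$necrotic_core) spec$core_fraction else 0),
      list(family = "ellipsoid", center = ctr2, radii = rep(r2, 3),
           rot = diag(3), r0 = r2, amp = 0,
           core_fraction = if (spec$necrotic_core) spec$core_fraction else 0))
  } else {
    for (i in seq_len(spec$lesion_count)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        if (spec$shape_family == "ellipsoid") {
          radii <- stats::runif(3, spec$radius_range[1], spec$radius_range[2])
          qr_ <- qr(matrix(stats::rnorm(9), 3))
          rot <- qr.Q(qr_)
          if (det(rot) < 0) rot[, 1] <- -rot[, 1]
          r0 <- max(radii); amp <- 0; coef <- NULL
        } else if (spec$shape_family == "sphere") {
          r0 <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
          radii <- rep(r0, 3); rot <- diag(3); amp <- 0; coef <- NULL
        } else {
          r0 <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
          radii <- rep(r0, 3); rot <- diag(3)
          amp <- spec$lobulation_amp
          coef <- stats::rnorm(5)
        }
        margin <- r0 * (1 + amp) + 2
        if (any(dimv - 2 * margin <= 0)) next
        ctr <- stats::runif(3, margin + 1, dimv - margin)
        ok <- all(vapply(shapes, function(s)
          sqrt(sum((ctr - s$center)^2)) >
            (r0 * (1 + amp) + s$r0 * (1 + s$amp) + 2), TRUE))
        if (ok) {
          shapes[[i]] <- list(family = spec$shape_family, center = ctr,
                              radii = radii, rot = rot, r0 = r0, amp = amp,
                              coef = coef,
                              core_fraction = if (spec$necrotic_core)
                                spec$core_fraction else 0)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place all lesions; increase volume_shape", call. = FALSE)
    }
  }
  labels <- array(0L, dimv)
  core_all <- array(FALSE, dimv)
  for (i in seq_along(shapes)) {
    rl <- rasterize_lesion(shapes[[i]], dimv, spec$spacing)
    labels[rl$mask & labels == 0L] <- i
    if (shapes[[i]]$core_fraction > 0) core_all <- core_all | rl$core
  }
  separator <- NULL
  if (spec$adjacency) {
    axis <- which(shapes[[2]]$center != shapes[[1]]$center)[1]
    t0 <- round(shapes[[1]]$center[axis] + shapes[[1]]$r0 - 0.5)
    for (width in 0:2) {
      separator <- array(FALSE, dimv)
      band <- clamp((t0 - width):(t0 + width), 1, dimv[axis])
      switch(axis, separator[band, , ] <- TRUE,
             separator[, band, ] <- TRUE, separator[, , band] <- TRUE)
      split <- apply_separators(labels > 0L, separator)
      if (max(cc_label(split, 26L)) >= 2L) break
    }
  }
  img <- array(spec$bg_mean, dimv)
  img[labels > 0L] <- spec$fg_mean
  img[core_all] <- spec$core_mean
  tex <- array(stats::rnorm(prod(dimv)), dimv)
  img <- img + tex * ifelse(labels > 0L, spec$fg_sd, spec$bg_sd)
  img <- gauss_blur3(img, spec$smoothing_sigma / spec$spacing)
  if (spec$noise_sd > 0)
    img <- img + array(stats::rnorm(prod(dimv), sd = spec$noise_sd), dimv)
  structure(list(volume = scalar_volume(img, spec$spacing),
                 labels = labels, separator = separator,
                 lesions = shapes, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels, %d lesion(s), %s%s, seed %d\n",
              paste(dim(x$labels), collapse = "x"), length(x$lesions),
              x$spec$shape_family,
              if (x$spec$necrotic_core) " + necrotic core" else "",
              x$spec$seed))
  invisible(x)
}

#' Generate a suite of phantoms
#'
#' Case `i` uses seed `seed * 1000 + i` and the `i`-th row (recycled) of
#' `difficulty_grid`, a data frame whose columns override [phantom_spec()]
#' fields (e.g. `shape_family`, `fg_mean`, `necrotic_core`,
#' `lobulation_amp`, `lesion_count`). With `dir` set, image/label NIfTI
#' pairs and a JSON manifest are written; otherwise phantoms are returned
#' in memory.
#'
#' @param n Number of cases.
#' @param base_spec Baseline [phantom_spec()].
#' @param difficulty_grid Data frame of per-case overrides, or `NULL`.
#' @param seed Suite seed.
#' @param dir Output directory, or `NULL` for in-memory phantoms.
#' @return A `phantom_suite`: list of `cases`, each with `case_id`, `spec`,
#'   and either `phantom` (in-memory) or `image` / `labels` paths.
#' @export
make_suite <- function(n, base_spec = phantom_spec(), difficulty_grid = NULL,
                       seed = 1L, dir = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- base_spec
    if (!is.null(difficulty_grid)) {
      row <- difficulty_grid[((i - 1L) %% nrow(difficulty_grid)) + 1L, ,
                             drop = FALSE]
      for (nm in names(row)) spec[[nm]] <- row[[nm]]
    }
    spec$seed <- as.integer(seed) * 1000L + i
    class(spec) <- "phantom_spec"
    ph <- make_phantom(spec)
    case <- list(case_id = sprintf("case_%03d", i), spec = spec)
    if (is.null(dir)) {
      case$phantom <- ph
    } else {
      fi <- file.path(dir, sprintf("case_%03d_image.nii.gz", i))
      fl <- file.path(dir, sprintf("case_%03d_labels.nii.gz", i))
      write_volume(ph$volume, fi)
      write_volume(array(as.integer(ph$labels), dim(ph$labels)), fl,
                   spacing = spec$spacing)
      case$image <- fi; case$labels <- fl
      if (!is.null(ph$separator)) {
        fs <- file.path(dir, sprintf("case_%03d_separator.nii.gz", i))
        write_volume(ph$separator, fs, spacing = spec$spacing)
        case$separator <- fs
      }
      case$lesion_centers <- lapply(ph$lesions, `[[`, "center")
    }
    cases[[i]] <- case
  }
  suite <- structure(list(cases = cases, seed = seed), class = "phantom_suite")
  if (!is.null(dir)) {
    mf <- lapply(cases, function(cs) {
      cs <- cs[setdiff(names(cs), "phantom")]
      cs$spec <- unclass(cs$spec)
      cs
    })
    jsonlite::write_json(mf, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    suite$dir <- dir
  }
  suite
}

#' Canonical difficulty grid for phantom suites
#'
#' The mix of conditions the evaluation suites cycle through: convex and
#' lobulated shapes at two lobulation amplitudes, with and without necrotic
#' cores, contrast-to-noise ratios of 10 and 20, and an 80/20 split of
#' solitary vs two-lesion cases (roughly the multiplicity mix seen in brain
#' tumour cohorts). Designed for a 56 voxel cube at 1 mm isotropic with
#' lesion radii 6-10 mm.
#'
#' @return Data frame of per-case [phantom_spec()] overrides.
#' @export
default_difficulty_grid <- function() {
  data.frame(
    shape_family = c("ellipsoid", "ellipsoid", "ellipsoid", "lobulated",
                     "lobulated", "lobulated", "lobulated", "lobulated",
                     "ellipsoid", "lobulated"),
    lobulation_amp = c(0, 0, 0, 0.2, 0.2, 0.35, 0.35, 0.35, 0, 0.2),
    necrotic_core = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                      FALSE, FALSE),
    fg_mean = c(100, 60, 100, 100, 60, 100, 100, 60, 100, 100),
    lesion_count = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L),
    stringsAsFactors = FALSE)
}

#' Baseline spec matching [default_difficulty_grid()]
#'
#' @return A [phantom_spec()] sized for the canonical grid.
#' @export
default_suite_spec <- function() {
  phantom_spec(volume_shape = c(56L, 56L, 56L), radius_range = c(6, 10))
}

#' Load a phantom from a suite case
#'
#' @param case One element of a `phantom_suite`'s `cases`.
#' @return List with `volume`, `labels`, `separator` (or `NULL`).
#' @export
load_case <- function(case) {
  if (!is.null(case$phantom)) {
    ph <- case$phantom
    return(list(volume = ph$volume, labels = ph$labels,
                separator = ph$separator))
  }
  vol <- read_volume(case$image)
  lab <- read_volume(case$labels)$data
  sep <- if (!is.null(case$separator)) read_mask(case$separator) else NULL
  list(volume = vol, labels = array(as.integer(round(lab)), dim(lab)),
       separator = sep)
}
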