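#' @title Scalar volumes, binary masks and multi-planar reformat slices
#'
#' @description Core 3D containers used throughout the package. A
#' `scalar_volume` is a 3D intensity lattice with per-axis voxel spacing (mm)
#' and the NIfTI affine carried through I/O. Binary masks are plain logical
#' arrays on the same grid as their companion volume.
#'
#' @section Coordinate convention:
#' Volumes are indexed `[x, y, z]`, 1-based (the R convention). The three
#' canonical multi-planar reformat (MPR) orientations fix one coordinate:
#' *axial* fixes `z` (in-plane axes `x`, `y`), *coronal* fixes `y` (in-plane
#' `x`, `z`), *sagittal* fixes `x` (in-plane `y`, `z`). In-plane points are
#' `(row, col)` pairs in the extracted 2D matrix, so for an axial plane
#' `row = x`, `col = y`. Volumes are used in their stored voxel grid; no
#' resampling to a canonical anatomical orientation is performed (inputs are
#' assumed co-registered).
#'
#' @section Physical units:
#' All lengths are computed in millimetres using `spacing`; on 1 mm isotropic
#' grids these coincide with voxel units.
#'
#' @name volumes
NULL

#' Construct a scalar volume
#'
#' @param data 3D numeric array of intensities, indexed `[x, y, z]`.
#' @param spacing Numeric length-3, strictly positive voxel size in mm.
#' @param affine Optional 4x4 voxel-to-world matrix (kept for round-tripping).
#' @return An object of class `scalar_volume` with fields `data`, `spacing`,
#'   `affine`.
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L) stop("expected 3D volume", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers", call. = FALSE)
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

## Accept either a scalar_volume or a bare array and return the array
vol_data <- function(vol) {
  if (inherits(vol, "scalar_volume")) vol$data else vol
}

vol_spacing <- function(vol) {
  if (inherits(vol, "scalar_volume")) vol$spacing else c(1, 1, 1)
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1/2 image into a [scalar_volume]. Intensities are not
#' rescaled or reordered.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [scalar_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("volume file not found: '%s'", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "failed to read NIfTI file '%s': %s", path,
                    conditionMessage(e)), call. = FALSE))
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- array(a, dim(a)[1:3])
  if (length(dim(a)) != 3L)
    stop(sprintf("expected 3D volume in '%s' (got %dD)", path,
                 length(dim(a))), call. = FALSE)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  sp[!is.finite(sp) | sp <= 0] <- 1
  scalar_volume(a, spacing = sp, affine = structure(RNifti::xform(img), code = NULL))
}

#' Write a 3D volume or mask to NIfTI
#'
#' Masks (logical arrays) are stored as unsigned 8-bit; intensity volumes as
#' their native numeric type. Spacing is written to `pixdim`.
#'
#' @param vol A [scalar_volume], or a logical/numeric 3D array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param spacing Voxel spacing, used when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing = c(1, 1, 1)) {
  if (inherits(vol, "scalar_volume")) {
    a <- vol$data
    spacing <- vol$spacing
  } else {
    a <- vol
  }
  datatype <- "auto"
  if (is.logical(a)) {
    a <- array(as.integer(a), dim(a))
    datatype <- "uint8"
  }
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI path; any nonzero voxel becomes `TRUE`.
#' @return Logical 3D array with attribute `spacing`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  m <- v$data != 0
  attr(m, "spacing") <- v$spacing
  m
}

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(vol_data(a)), dim(vol_data(b))))
    stop("grid mismatch: arrays have different dimensions", call. = FALSE)
}

plane_axes <- list(axial    = c(1L, 2L),  # fixed z
                   coronal  = c(1L, 3L),  # fixed y
                   sagittal = c(2L, 3L))  # fixed x

plane_fixed_axis <- c(axial = 3L, coronal = 2L, sagittal = 1L)

#' Extract a 2D plane from a volume
#'
#' @param vol A [scalar_volume] or a 3D array (e.g. a mask).
#' @param orientation One of `"axial"`, `"coronal"`, `"sagittal"`.
#' @param index 1-based position along the out-of-plane axis.
#' @return A `plane_slice`: list with `data` (2D matrix), `orientation`,
#'   `fixed_index`, and `spacing` (in-plane mm per pixel, length 2). Use
#'   [plane_to3d()] to map in-plane `(row, col)` back to voxel indices.
#' @export
extract_plane <- function(vol, orientation = c("axial", "coronal", "sagittal"),
                          index) {
  orientation <- match.arg(orientation)
  a <- vol_data(vol)
  sp <- vol_spacing(vol)
  ax <- plane_fixed_axis[[orientation]]
  if (!(index >= 1L && index <= dim(a)[ax]))
    stop(sprintf("plane index %d out of range [1, %d] for %s orientation",
                 index, dim(a)[ax], orientation), call. = FALSE)
  d <- switch(orientation,
              axial    = a[, , index],
              coronal  = a[, index, ],
              sagittal = a[index, , ])
  inpl <- plane_axes[[orientation]]
  structure(list(data = d, orientation = orientation,
                 fixed_index = as.integer(index), spacing = sp[inpl]),
            class = "plane_slice")
}

#' Map in-plane coordinates back to 3D voxel indices
#'
#' The inverse of [extract_plane()]: `(row, col)` in the plane's 2D matrix is
#' mapped to the `(x, y, z)` voxel it came from. Accepts a vector of length 2
#' or an n x 2 matrix; values may be fractional (continuous points).
#'
#' @param plane A `plane_slice`.
#' @param rc Length-2 vector or n x 2 matrix of `(row, col)` coordinates.
#' @return Length-3 vector or n x 3 matrix of `(x, y, z)` coordinates.
#' @export
plane_to3d <- function(plane, rc) {
  one <- is.null(dim(rc))
  rc <- rbind(rc)
  k <- plane$fixed_index
  out <- switch(plane$orientation,
                axial    = cbind(rc[, 1], rc[, 2], k),
                coronal  = cbind(rc[, 1], k, rc[, 2]),
                sagittal = cbind(k, rc[, 1], rc[, 2]))
  colnames(out) <- c("x", "y", "z")
  if (one) out[1, ] else out
}

#' Project a 3D voxel coordinate into a plane's (row, col) frame
#'
#' @param plane A `plane_slice`.
#' @param xyz Length-3 vector or n x 3 matrix.
#' @return Length-2 vector or n x 2 matrix of in-plane `(row, col)`.
#' @export
plane_from3d <- function(plane, xyz) {
  one <- is.null(dim(xyz))
  xyz <- rbind(xyz)
  inpl <- plane_axes[[plane$orientation]]
  out <- xyz[, inpl, drop = FALSE]
  colnames(out) <- c("row", "col")
  if (one) out[1, ] else out
}

#' @export
print.plane_slice <- function(x, ...) {
  cat(sprintf("<plane_slice> %s @ %d, %s pixels\n", x$orientation,
              x$fixed_index, paste(dim(x$data), collapse = "x")))
  invisible(x)
}

#' Extract the axial/coronal/sagittal trio through a point
#'
#' The centre of the long axis is typically used to centre the reformatted
#' coronal and sagittal planes of the 3-plane MPR view.
#'
#' @param vol A [scalar_volume] or 3D array.
#' @param point Length-3 voxel coordinate (may be fractional; it is rounded
#'   to the nearest voxel, clamped to the grid).
#' @return Named list of three `plane_slice`s: `axial`, `coronal`, `sagittal`.
#' @export
mpr_at <- function(vol, point) {
  a <- vol_data(vol)
  d <- dim(a)
  p <- round(as.numeric(point))
  if (length(p) != 3L || any(p < 1) || any(p > d))
    stop(sprintf("point (%s) outside volume bounds %s",
                 paste(format(point), collapse = ", "),
                 paste(d, collapse = "x")), call. = FALSE)
  list(axial    = extract_plane(vol, "axial",    p[3]),
       coronal  = extract_plane(vol, "coronal",  p[2]),
       sagittal = extract_plane(vol, "sagittal", p[1]))
}
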