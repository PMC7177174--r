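#' @title Lesion preparation: label merging, separators, enumeration
#'
#' @description Ground-truth label volumes (e.g. BraTS-style masks with
#' several tissue phenotypes) are reduced to a single binary target mask,
#' optionally split by a manually drawn separator mask where distinct lesions
#' adjoin, and enumerated into per-lesion records by 3D connected-component
#' analysis.
#' @name lesion_prep
NULL

#' Merge label values into a binary mask
#'
#' For BraTS-style data the necrotic/non-enhancing core and the enhancing
#' tumour labels are typically merged into one "core tumour" target, leaving
#' oedema out.
#'
#' @param labels 3D integer array (0 = background) or [scalar_volume].
#' @param keep Nonempty vector of label values to include.
#' @return Logical 3D array: `TRUE` where the label is in `keep`.
#' @export
merge_labels <- function(labels, keep) {
  if (length(keep) == 0L) stop("keep must be nonempty", call. = FALSE)
  a <- vol_data(labels)
  array(a %in% keep, dim(a))
}

#' Blank separator voxels out of a mask
#'
#' Separators are zero-valued lines/planes drawn to split adjoining lesions
#' before connected-component enumeration.
#'
#' @param mask Logical 3D array.
#' @param separators Logical 3D array on the same grid.
#' @return `mask` with separator voxels forced `FALSE`.
#' @export
apply_separators <- function(mask, separators) {
  stopifnot_same_grid(mask, separators)
  mask & !separators
}

#' Enumerate lesions by 3D connected-component analysis
#'
#' Each distinct "island" of the mask becomes a `lesion_record`. Records are
#' ordered by descending voxel count (ties broken by lexicographic bounding
#' box minimum) and given ids `1..K`. Components smaller than `min_voxels`
#' are retained but flagged `small = TRUE`; nothing is silently dropped.
#'
#' @param mask Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26: face, edge and corner
#'   neighbours all connect).
#' @param min_voxels Flag threshold for small components.
#' @return List of `lesion_record` objects, each with `lesion_id`, `mask`,
#'   `bbox` (2 x 3 inclusive bounds), `slice_range` (inclusive z range of
#'   nonempty axial slices), `voxel_count`, `small`.
#' @export
enumerate_lesions <- function(mask, connectivity = 26L, min_voxels = 10L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  lab <- cc_label(mask, connectivity)
  k <- max(lab)
  if (k == 0L) return(list())
  recs <- lapply(seq_len(k), function(i) {
    m <- lab == i
    co <- which_coords(m)
    bbox <- rbind(min = apply(co, 2, min), max = apply(co, 2, max))
    colnames(bbox) <- c("x", "y", "z")
    list(mask = m, bbox = bbox,
         slice_range = c(bbox["min", "z"], bbox["max", "z"]),
         voxel_count = nrow(co))
  })
  ord <- order(-vapply(recs, `[[`, 0L, "voxel_count"),
               vapply(recs, function(r) r$bbox["min", "x"], 0L),
               vapply(recs, function(r) r$bbox["min", "y"], 0L),
               vapply(recs, function(r) r$bbox["min", "z"], 0L))
  recs <- recs[ord]
  for (i in seq_along(recs)) {
    recs[[i]]$lesion_id <- i
    recs[[i]]$small <- recs[[i]]$voxel_count < min_voxels
    class(recs[[i]]) <- "lesion_record"
  }
  recs
}

#' @export
print.lesion_record <- function(x, ...) {
  cat(sprintf("<lesion_record> id %d: %d voxels, slices [%d, %d]%s\n",
              x$lesion_id, x$voxel_count, x$slice_range[1], x$slice_range[2],
              if (isTRUE(x$small)) " (small)" else ""))
  invisible(x)
}

#' Choose the axial slice on which the simulated user draws
#'
#' Emulates a radiologist scrolling for the slice where the lesion looks
#' largest: among the central third of the lesion's axial slice range, the
#' slice with the largest ground-truth area is chosen (ties go to the lowest
#' index).
#'
#' For a slice range `[a, b]` with `n = b - a + 1` slices the central-third
#' subset is `[a + floor(n/3), a + ceil(2n/3) - 1]`, which is always
#' nonempty and degenerates to the single slice when `n = 1`.
#'
#' @param lesion A `lesion_record` from [enumerate_lesions()].
#' @return Integer axial slice index.
#' @export
select_axial_slice <- function(lesion) {
  a <- lesion$slice_range[1]; b <- lesion$slice_range[2]
  n <- b - a + 1L
  lo <- a + floor(n / 3)
  hi <- a + ceiling(2 * n / 3) - 1L
  zs <- lo:hi
  areas <- vapply(zs, function(z) sum(lesion$mask[, , z]), 0L)
  zs[which.max(areas)]   # which.max takes the first (lowest) on ties
}

#' Write per-lesion masks and a JSON manifest
#'
#' @param lesions List of `lesion_record`s.
#' @param dir Output directory (created if needed).
#' @param spacing Voxel spacing written to the NIfTI headers.
#' @return Path to the manifest JSON, invisibly.
#' @export
write_lesion_manifest <- function(lesions, dir, spacing = c(1, 1, 1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(lesions, function(l) {
    f <- file.path(dir, sprintf("lesion_%03d.nii.gz", l$lesion_id))
    write_volume(l$mask, f, spacing = spacing)
    list(lesion_id = l$lesion_id, mask = basename(f),
         bbox_min = unname(l$bbox["min", ]), bbox_max = unname(l$bbox["max", ]),
         slice_range = l$slice_range, voxel_count = l$voxel_count,
         small = isTRUE(l$small),
         chosen_axial_slice = select_axial_slice(l))
  })
  mf <- file.path(dir, "lesions.json")
  jsonlite::write_json(entries, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}
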