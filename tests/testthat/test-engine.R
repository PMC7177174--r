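test_that("2D segmentation recovers a bright disc from its diameter", {
  set.seed(1)
  gt <- disc2d(64, c(32, 32), 14)
  img <- matrix(20, 64, 64); img[gt] <- 100
  img <- img + matrix(rnorm(64^2, 0, 2), 64)
  eng <- make_engine()
  seg <- eng$segment_2d(img, interaction_input(axes = list(
    axis_line(c(32, 18), c(32, 46)))))
  expect_gte(dsc(seg, gt), 0.95)
  # deterministic
  seg2 <- eng$segment_2d(img, interaction_input(axes = list(
    axis_line(c(32, 18), c(32, 46)))))
  expect_identical(seg, seg2)
})

test_that("2D contracts: connected, contains the axis, bounded by the ROI", {
  set.seed(2)
  img <- matrix(50, 48, 48) + matrix(rnorm(48^2, 0, 0.5), 48)
  ax <- axis_line(c(24, 14), c(24, 34))
  eng <- make_engine()
  seg <- eng$segment_2d(img, interaction_input(axes = list(ax)))
  # contains every axis pixel
  px <- cbind(24, 14:34)
  expect_true(all(seg[px]))
  # connected
  expect_equal(max(cc_label(seg, 8L)), 1)
  # within the ROI bound (radius <= factor x axis length)
  co <- which(seg, arr.ind = TRUE)
  dmax <- max(sqrt((co[, 1] - 24)^2 + (co[, 2] - 24)^2))
  expect_lte(dmax, 1.5 * ax$length_mm + 1)
  expect_error(eng$segment_2d(img, interaction_input()), "axis")
  expect_error(eng$segment_2d(img, interaction_input(axes = list(
    axis_line(c(-3, 2), c(24, 34))))), "outside")
})

test_that("dropped points pull the contour within tolerance", {
  # two overlapping lobes of different brightness; the axis covers the
  # bright lobe, a drop on the dim lobe's far boundary recovers it
  A <- disc2d(64, c(32, 24), 10); B <- disc2d(64, c(32, 38), 8)
  gt <- A | B
  img <- matrix(20, 64, 64); img[A] <- 100; img[B] <- 60
  set.seed(1); img <- img + matrix(rnorm(64^2, 0, 2), 64)
  eng <- make_engine()
  ax <- axis_line(c(32, 14), c(32, 34))
  s0 <- eng$segment_2d(img, interaction_input(axes = list(ax)))
  d0 <- dsc(s0, gt)
  drop <- c(32, 46)   # on the true boundary of the missed lobe
  s1 <- eng$segment_2d(img, interaction_input(axes = list(ax),
                                              drops = rbind(drop)))
  expect_gt(dsc(s1, gt), d0)
  bnd <- boundary_points(s1)
  expect_lte(min(sqrt((bnd[, 1] - drop[1])^2 + (bnd[, 2] - drop[2])^2)), 1.5)
  expect_length(attr(s1, "constraint_violations"), 0)
})

test_that("scout stage segments the reformatted planes from the 2D result", {
  sp <- sphere_phantom(seed = 3, n = 48, r = 14)
  les <- lesion_from_mask(sp$gt)
  k <- select_axial_slice(les)
  eng <- make_engine()
  img_ax <- extract_plane(sp$vol, "axial", k)$data
  gt_ax <- extract_plane(sp$gt, "axial", k)$data
  ax <- true_longest_axis(gt_ax)
  seg2 <- eng$segment_2d(img_ax, interaction_input(axes = list(ax)))
  mid <- plane_to3d(extract_plane(sp$vol, "axial", k), (ax$p0 + ax$p1) / 2)
  st <- seg_state("2d", plane_masks = list(axial = seg2),
                  plane_index = c(axial = k), mid3 = mid,
                  interaction = list(axial = interaction_input(axes = list(ax))))
  scout <- eng$segment_scout(sp$vol, st)
  expect_equal(scout$stage, "scout")
  # axial mask passes through unchanged
  expect_identical(scout$plane_masks$axial, seg2)
  for (plane in c("coronal", "sagittal")) {
    gp <- extract_plane(sp$gt, plane, scout$plane_index[[plane]])$data
    expect_gte(dsc(scout$plane_masks[[plane]], gp), 0.9)
  }
  # a user long axis on the coronal plane is honoured
  gt_co <- extract_plane(sp$gt, "coronal", scout$plane_index[["coronal"]])$data
  ax_co <- true_longest_axis(gt_co)
  scout2 <- eng$segment_scout(sp$vol, st,
                              list(coronal = interaction_input(axes = list(ax_co))))
  px <- rbind(round(ax_co$p0), round(ax_co$p1))
  expect_true(all(scout2$plane_masks$coronal[px]))
})

test_that("3D stage recovers a sphere, contains its seeds, and is deterministic", {
  sp <- sphere_phantom(seed = 5, n = 48, r = 15, fg = 45, bg = 20, noise = 5)
  les <- lesion_from_mask(sp$gt)   # CNR = 5
  run <- function() simulate_lesion(sp$vol, les, "LONG_AXIAL", "true_longest")
  r1 <- run(); r2 <- run()
  expect_gte(r1$stage_dsc[["d3"]], 0.90)
  expect_identical(r1$mask, r2$mask)   # bit-identical reruns
  # seed containment: the 3D mask holds every plane-mask voxel
  st <- r1$state
  for (plane in names(st$plane_masks)) {
    pm <- st$plane_masks[[plane]]
    idx <- st$plane_index[[plane]]
    got <- extract_plane(st$volume_mask, plane, idx)$data
    expect_true(all(got[pm]))
  }
  # single 26-connected component
  expect_equal(max(cc_label(st$volume_mask, 26L)), 1)
  # accuracy falls off moderately across stages, not catastrophically
  expect_lte(abs(r1$stage_dsc[["d3"]] - r1$stage_dsc[["d2"]]), 0.1)
})

test_that("the engine API is pluggable", {
  # a minimal threshold engine honouring the stage contracts
  threshold_engine <- function(config) {
    seg2 <- function(img2, inter, spacing = c(1, 1)) {
      ax <- inter$axes[[1]]
      cut <- mean(bilinear_sample(img2, segment_points(ax$p0, ax$p1))) / 2
      m <- img2 > cut
      m[rbind(round(ax$p0), round(ax$p1))] <- TRUE
      m
    }
    list(config = config,
         segment_2d = seg2,
         segment_scout = function(vol, state, mpr = list()) {
           mid <- round(state$mid3)
           state$plane_index <- c(axial = unname(state$plane_index[["axial"]]),
                                  coronal = unname(mid[2]),
                                  sagittal = unname(mid[1]))
           for (p in c("coronal", "sagittal")) {
             img2 <- extract_plane(vol, p, state$plane_index[[p]])$data
             state$plane_masks[[p]] <- img2 > mean(img2)
           }
           state$stage <- "scout"
           state
         },
         segment_3d = function(vol, state) {
           a <- if (inherits(vol, "scalar_volume")) vol$data else vol
           state$volume_mask <- a > mean(a)
           state$stage <- "3d"
           state
         })
  }
  register_engine("threshold_test", threshold_engine)
  eng <- make_engine("threshold_test")
  sp <- sphere_phantom(seed = 8, n = 40, r = 11)
  les <- lesion_from_mask(sp$gt)
  res <- simulate_lesion(sp$vol, les, "LONG_AXIAL", "true_longest",
                         engine = eng)
  expect_gte(res$stage_dsc[["d3"]], 0.8)
  expect_error(make_engine("no_such_engine"), "unknown engine")
})
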