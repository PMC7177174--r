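test_that("worst disagreement point matches the exhaustive oracle", {
  gt <- rect2d(32, 6:25, 6:25)
  seg <- gt
  expect_null(worst_disagreement_point(seg, gt))
  # a 6x6 corner bite: the farthest gt boundary point is the bitten corner
  seg2 <- gt; seg2[20:25, 20:25] <- FALSE
  p <- worst_disagreement_point(seg2, gt)
  o <- oracle_worst_point(seg2, gt)
  expect_equal(unname(p), unname(o$point))
  expect_equal(unname(p), c(25, 25))
  # spacing exclusion forces the second-best point (compare by disagreement
  # distance: the argmax may tie across symmetric points)
  p2 <- worst_disagreement_point(seg2, gt, existing = rbind(p),
                                 policy = drop_policy(min_spacing_px = 3))
  o2 <- oracle_worst_point(seg2, gt, existing = rbind(p), min_spacing = 3)
  S <- boundary_points(seg2)
  dist_of <- function(q) min(sqrt((S[, 1] - q[1])^2 + (S[, 2] - q[2])^2))
  expect_equal(dist_of(p2), o2$dist)
  expect_gte(sqrt(sum((p2 - p)^2)), 3)
  # below the disagreement threshold, nothing is returned
  seg3 <- gt; seg3[6, 6] <- FALSE
  expect_null(worst_disagreement_point(
    seg3, gt, policy = drop_policy(disagreement_threshold_px = 3)))
})

test_that("worst disagreement matches the oracle on random mask pairs", {
  for (seed in 1:15) {
    gt <- random_blob2d(seed + 200)
    seg <- random_blob2d(seed + 300)
    p <- worst_disagreement_point(seg, gt,
                                  policy = drop_policy(disagreement_threshold_px = 0.5))
    o <- oracle_worst_point(seg, gt, threshold = 0.5)
    if (is.null(o)) {
      expect_null(p)
    } else {
      # equal disagreement distance (the argmax point may tie)
      G <- boundary_points(gt); S <- boundary_points(seg)
      dist_of <- function(q) min(sqrt((S[, 1] - q[1])^2 + (S[, 2] - q[2])^2))
      expect_equal(dist_of(p), o$dist)
    }
  }
})

test_that("the drop loop terminates, respects the policy, and helps", {
  A <- disc2d(64, c(32, 24), 10); B <- disc2d(64, c(32, 38), 8)
  gt <- A | B
  img <- matrix(20, 64, 64); img[A] <- 100; img[B] <- 60
  set.seed(1); img <- img + matrix(rnorm(64^2, 0, 2), 64)
  eng <- make_engine()
  ax <- axis_line(c(32, 14), c(32, 34))
  s0 <- eng$segment_2d(img, interaction_input(axes = list(ax)))
  reseg <- function(dr) eng$segment_2d(img, interaction_input(axes = list(ax),
                                                              drops = dr))
  res <- drop_points_loop(s0, gt, reseg, drop_policy())
  expect_gt(dsc(res$mask, gt), dsc(s0, gt))
  expect_lte(nrow(res$drops), drop_policy()$max_drops)
  if (nrow(res$drops) >= 1) {
    # every drop lies on the gt boundary
    G <- boundary_points(gt)
    for (i in seq_len(nrow(res$drops)))
      expect_lte(min(sqrt((G[, 1] - res$drops[i, 1])^2 +
                          (G[, 2] - res$drops[i, 2])^2)), 1)
  }
  if (nrow(res$drops) >= 2) {
    dd <- as.matrix(dist(res$drops))
    expect_gte(min(dd[upper.tri(dd)]), drop_policy()$min_spacing_px)
  }
  # perfect segmentation: no drops
  res0 <- drop_points_loop(gt, gt, reseg, drop_policy())
  expect_equal(nrow(res0$drops), 0)
  expect_identical(res0$mask, gt)
  # zero cap: state unchanged
  resc <- drop_points_loop(s0, gt, reseg, drop_policy(max_drops = 0))
  expect_identical(resc$mask, s0)
})

test_that("edit to perfection replaces plane contours with ground truth", {
  sp <- sphere_phantom(seed = 6, n = 40, r = 10)
  les <- lesion_from_mask(sp$gt)
  res <- simulate_lesion(sp$vol, les, "LONG_AXIAL", "true_longest")
  st <- edit_to_perfection(res$state, sp$gt)
  for (plane in c("axial", "coronal", "sagittal")) {
    gp <- extract_plane(sp$gt, plane, st$plane_index[[plane]])$data
    expect_equal(dsc(st$plane_masks[[plane]], gp), 1)
  }
  # a plane missed by the lesion is emptied but 3D still runs off the others
  st2 <- res$state
  empty_gt <- array(FALSE, dim(sp$gt))
  empty_gt[st2$plane_index[["sagittal"]] + 5, , ] <- TRUE  # elsewhere only
  st3 <- edit_to_perfection(st2, empty_gt, planes = "sagittal")
  expect_false(any(st3$plane_masks$sagittal))
  eng <- make_engine()
  st3$stage <- "scout"
  out <- eng$segment_3d(sp$vol, st3)
  expect_gt(sum(out$volume_mask), 0)
})

test_that("simulated lesions meet the accuracy bar and replay bit-exactly", {
  sp <- sphere_phantom(seed = 12, n = 48, r = 13)
  les <- lesion_from_mask(sp$gt)
  res <- simulate_lesion(sp$vol, les, "LONG_AXIAL", "true_longest")
  expect_gte(res$stage_dsc[["d3"]], 0.85)
  expect_identical(replay_trace(sp$vol, res$trace), res$mask)
  # a drops-level trace replays exactly too
  res2 <- simulate_lesion(sp$vol, les, "LONG_SHORT_DROPS_MPR", "true_longest")
  expect_identical(replay_trace(sp$vol, res2$trace), res2$mask)
})

test_that("interaction levels draw exactly the actions they advertise", {
  sp <- sphere_phantom(seed = 13, n = 44, r = 11)
  les <- lesion_from_mask(sp$gt)
  res <- simulate_lesion(sp$vol, les, "LONG_MPR", "true_longest")
  types <- vapply(res$trace$actions, `[[`, "", "type")
  expect_equal(sum(types == "long_axis"), 3)   # one per plane
  expect_false(any(types %in% c("short_axis", "drop", "edit_to_perfection")))
  resP <- simulate_lesion(sp$vol, les, "PERFECT_AXIAL", "true_longest")
  typesP <- vapply(resP$trace$actions, `[[`, "", "type")
  expect_true("edit_to_perfection" %in% typesP)
  expect_equal(resP$stage_dsc[["d2"]], 1)
})

test_that("patient-level union aggregates per-lesion masks", {
  d <- c(64, 64, 28)
  b1 <- ball3d(d, c(18, 18, 14), 9)
  b2 <- ball3d(d, c(46, 46, 14), 8)
  gt <- b1 | b2
  set.seed(2)
  img <- array(20, d); img[gt] <- 100
  img <- img + array(rnorm(prod(d), 0, 2), d)
  vol <- scalar_volume(img)
  lesions <- enumerate_lesions(gt)
  expect_length(lesions, 2)
  one <- simulate_patient(vol, lesions[1])
  expect_identical(one$mask, simulate_lesion(vol, lesions[[1]])$mask)
  both <- simulate_patient(vol, lesions)
  m1 <- simulate_lesion(vol, lesions[[1]])$mask
  m2 <- simulate_lesion(vol, lesions[[2]])$mask
  expect_identical(both$mask, m1 | m2)
  # disjoint lesions: union count is the sum of parts
  expect_equal(sum(both$mask), sum(m1) + sum(m2))
  # overlapping results count each voxel once
  expect_equal(sum(m1 | m1), sum(m1))
  expect_error(simulate_patient(vol, list()), "at least one")
})
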