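test_that("boundary extraction matches the 8-adjacency definition", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(unclass(boundary_points(one))[1, ], c(3, 3),
               ignore_attr = TRUE)
  sq <- rect2d(9, 3:7, 3:7)
  bp <- boundary_points(sq)
  expect_equal(nrow(bp), 16)  # 5x5 square: 16 perimeter pixels
  expect_setequal(paste(bp[, 1], bp[, 2]),
                  paste(oracle_boundary(sq)[, 1], oracle_boundary(sq)[, 2]))
  expect_error(boundary_points(matrix(FALSE, 4, 4)), "empty")
})

test_that("ring masks report outer contour before inner", {
  ring <- disc2d(31, c(16, 16), 12) & !disc2d(31, c(16, 16), 7)
  bp <- boundary_points(ring)
  cid <- attr(bp, "contour")
  expect_gte(max(cid), 2)
  # the first contour holds the outermost pixels
  expect_equal(min(bp[cid == 1, 1]), min(bp[, 1]))
  r1 <- sqrt((bp[cid == 1, 1] - 16)^2 + (bp[cid == 1, 2] - 16)^2)
  r2 <- sqrt((bp[cid == 2, 1] - 16)^2 + (bp[cid == 2, 2] - 16)^2)
  expect_gt(min(r1), max(r2) - 1e-9)
})

test_that("true longest axis equals brute force on canonical shapes", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(true_longest_axis(one)$length_mm, 0)
  rect <- rect2d(16, 5:8, 3:12)   # 4 rows x 10 cols
  expect_equal(true_longest_axis(rect)$length_mm, sqrt(90))
  disc <- disc2d(48, c(24, 24), 20)
  expect_lt(abs(true_longest_axis(disc)$length_mm - 40), 1)
})

test_that("true longest axis equals the pairwise oracle on random blobs", {
  for (seed in 1:40) {
    m <- random_blob2d(seed)
    ax <- true_longest_axis(m)
    expect_equal(ax$length_mm^2, oracle_longest_len2(m))
  }
})

test_that("PCA ellipse recovers centre, orientation and axis lengths", {
  e0 <- ellipse_mask2d(64, c(32, 32), 20, 10)
  f0 <- fit_ellipse_pca(e0)
  expect_lt(min(f0$orientation_deg, 180 - f0$orientation_deg), 2)
  expect_lt(max(abs(f0$center - c(32, 32))), 0.5)
  expect_lt(abs(f0$major_len - 40) / 40, 0.05)
  expect_lt(abs(f0$minor_len - 20) / 20, 0.05)
  e30 <- ellipse_mask2d(64, c(32, 32), 20, 10, theta_deg = 30)
  f30 <- fit_ellipse_pca(e30)
  expect_lt(abs(f30$orientation_deg - 30), 2)
  disc <- disc2d(48, c(24, 24), 15)
  fd <- fit_ellipse_pca(disc)
  expect_lt(abs(fd$major_len - fd$minor_len) / fd$major_len, 0.05)
  line <- matrix(FALSE, 10, 10); line[3, 2:9] <- TRUE
  expect_error(fit_ellipse_pca(line), "collinear")
  expect_error(fit_ellipse_pca(matrix(FALSE, 5, 5)), "small")
})

test_that("medial long axis is the longest chord at the ellipse orientation", {
  e0 <- ellipse_mask2d(64, c(32, 32), 20, 10)
  ax <- medial_long_axis(e0)
  expect_lt(abs(ax$length_mm - 40), 1)
  mid <- (ax$p0 + ax$p1) / 2
  expect_lt(max(abs(mid - c(32, 32))), 1.5)   # chord through the centre
  disc <- disc2d(48, c(24, 24), 15)
  expect_lt(abs(medial_long_axis(disc)$length_mm - 30), 1.2)
})

test_that("medial chord matches the slab-constrained pair oracle", {
  for (seed in 1:25) {
    m <- random_blob2d(seed + 500)
    ell <- tryCatch(fit_ellipse_pca(m), error = function(e) NULL)
    if (is.null(ell)) next
    ax <- medial_long_axis(m, ell)
    expect_equal(ax$length_mm^2, oracle_chord_len2(m, ell$orientation_deg))
  }
})

test_that("crescents separate the medial axis from the true longest axis", {
  cres <- disc2d(64, c(32, 32), 20) & !disc2d(64, c(22, 32), 16)
  tl <- true_longest_axis(cres)
  ml <- medial_long_axis(cres)
  ell <- fit_ellipse_pca(cres)
  ang <- function(a) {
    v <- a$p1 - a$p0
    (atan2(v[2], v[1]) * 180 / pi) %% 180
  }
  dang <- abs(ang(ml) - ell$orientation_deg)
  expect_lt(min(dang, 180 - dang), 1e-6)   # parallel to the PCA major axis
  expect_gt(sum(abs(tl$p0 - ml$p0)) + sum(abs(tl$p1 - ml$p1)), 0)
})

test_that("short axis is the longest perpendicular chord", {
  rect <- rect2d(24, 6:17, 4:21)  # 12 rows x 18 cols
  long <- axis_line(c(11.5, 4), c(11.5, 21))
  sa <- short_axis(rect, long)
  expect_equal(sa$length_mm, 11)  # rectangle height in pixel units
  v <- sa$p1 - sa$p0
  expect_equal(abs(v[2]), 0)      # vertical chord
  disc <- disc2d(48, c(24, 24), 15)
  dl <- true_longest_axis(disc)
  expect_lt(abs(short_axis(disc, dl)$length_mm - 30), 1.2)
  e0 <- ellipse_mask2d(64, c(32, 32), 20, 10)
  sa2 <- short_axis(e0, medial_long_axis(e0))
  expect_lt(abs(sa2$length_mm - 20), 1)
  expect_error(short_axis(e0, axis_line(c(3, 3), c(3, 3))), "zero length")
})

test_that("short axis matches the perpendicular pair oracle on random blobs", {
  for (seed in 1:25) {
    m <- random_blob2d(seed + 900)
    long <- true_longest_axis(m)
    if (long$length_mm == 0) next
    sa <- short_axis(m, long)
    v <- long$p1 - long$p0
    theta <- (atan2(v[2], v[1]) * 180 / pi + 90) %% 180
    expect_equal(sa$length_mm^2, oracle_chord_len2(m, theta))
  }
})

test_that("candidate points are centred on the medial endpoints and on the boundary", {
  disc <- disc2d(64, c(32, 32), 20)
  med <- medial_long_axis(disc)
  cs <- candidate_points(disc, med, axis_score_params(N = 8))
  expect_equal(cs$r, 4)
  expect_equal(nrow(cs$side0), 9)
  # index r maps to the medial endpoints
  expect_lt(sqrt(sum((cs$side0[cs$r + 1, ] - med$p0)^2)), 1.5)
  expect_lt(sqrt(sum((cs$side1[cs$r + 1, ] - med$p1)^2)), 1.5)
  bp <- boundary_points(disc)
  key <- paste(bp[, 1], bp[, 2])
  expect_true(all(paste(cs$side0[, 1], cs$side0[, 2]) %in% key))
  expect_true(all(paste(cs$side1[, 1], cs$side1[, 2]) %in% key))
  # all candidates distinct
  expect_false(anyDuplicated(rbind(cs$side0)) > 0)
  # N = 2 still yields distinct neighbours adjacent to each endpoint
  cs2 <- candidate_points(disc, med, axis_score_params(N = 2, spacing_deg = 3))
  expect_equal(nrow(cs2$side0), 3)
  expect_false(anyDuplicated(cs2$side0) > 0)
})
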