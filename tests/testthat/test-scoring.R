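test_that("Parzen estimates are normalised and shaped as expected", {
  grid <- seq(0, 200, length.out = 256)
  dx <- grid[2] - grid[1]
  p1 <- parzen_pdf(80, bandwidth = 5, grid = grid)
  expect_equal(sum(p1$density) * dx, 1, tolerance = 1e-6)
  expect_equal(grid[which.max(p1$density)], 80, tolerance = dx)
  # two equal clusters split the mass evenly
  set.seed(4)
  s <- c(rnorm(250, 40, 5), rnorm(250, 160, 5))
  p2 <- parzen_pdf(s, bandwidth = 5, grid = grid)
  half <- sum(p2$density[grid < 100]) * dx
  expect_lt(abs(half - 0.5), 0.05)
  # random sample sets stay normalised
  for (seed in 1:5) {
    set.seed(seed)
    p <- parzen_pdf(runif(50, 10, 190), bandwidth = 3, grid = grid)
    expect_equal(sum(p$density) * dx, 1, tolerance = 1e-6)
  }
  expect_error(parzen_pdf(numeric(0), 5, grid), "sample")
  expect_error(parzen_pdf(5, 0, grid), "bandwidth")
})

test_that("KL divergence matches direct summation and its axioms", {
  grid <- 0:2
  mkpdf <- function(mass) structure(list(grid = grid, density = mass,
                                         bandwidth = 1),
                                    class = "intensity_pdf")
  P <- mkpdf(c(0.5, 0.25, 0.25)); Q <- mkpdf(c(0.25, 0.5, 0.25))
  expect_equal(kl_divergence(P, P), 0, tolerance = 1e-9)
  expect_equal(kl_divergence(P, Q), 0.25 * log(2), tolerance = 1e-6)
  set.seed(9)
  for (i in 1:20) {
    p <- runif(8); q <- runif(8)
    Pp <- mkpdf(p / sum(p)); Qq <- mkpdf(q / sum(q))
    expect_equal(kl_divergence(Pp, Qq), oracle_kl(p, q), tolerance = 1e-12)
    expect_gte(kl_divergence(Pp, Qq), 0)
  }
  other_grid <- structure(list(grid = c(0, 1, 3), density = c(0.5, 0.25, 0.25),
                               bandwidth = 1), class = "intensity_pdf")
  expect_error(kl_divergence(P, other_grid), "grid")
})

test_that("exact Parzen estimator agrees with the loop oracle", {
  grid <- seq(0, 100, length.out = 64)
  set.seed(2)
  s <- runif(30, 20, 80)
  p <- parzen_pdf(s, bandwidth = 4, grid = grid)
  expect_equal(p$density, oracle_parzen(s, 4, grid), tolerance = 1e-10)
})

test_that("centrality term reproduces the worked values and stays in range", {
  expect_equal(centrality_term(4, 4, 4), 0.1)          # i = j = r
  expect_equal(centrality_term(10, 6, 8), 0.325)       # opposite sides
  expect_equal(centrality_term(10, 10, 8), 0.2125)     # same side, halved
  for (r in c(1, 2, 4, 8)) {
    g <- expand.grid(i = 0:(2 * r), j = 0:(2 * r))
    v <- centrality_term(g$i, g$j, r)
    expect_true(all(v >= 0.1 - 1e-12 & v <= 1 + 1e-12))
    vi <- centrality_term(g$i, g$j, r, invert = TRUE)
    expect_true(all(vi >= 0.1 - 1e-12 & vi <= 1 + 1e-12))
  }
  expect_error(centrality_term(0, 0, 0), "positive")
  expect_error(centrality_term(9, 0, 4), "indices")
})

test_that("the axis score degenerates as the weights dictate", {
  img <- matrix(100, 48, 48)
  disc <- disc2d(48, c(24, 24), 15)
  tl <- true_longest_axis(disc)
  # homogeneous intensity: divergence 0, so score = alpha + beta + gamma*0.1
  prm <- axis_score_params(alpha = 0.5, beta = 0.3, gamma = 0.2, N = 8)
  sc <- score_axis(tl, 4, 4, disc, img, tl$length_mm, prm)
  expect_equal(sc, 0.5 + 0.3 + 0.2 * 0.1, tolerance = 1e-6)
  set.seed(7)
  img <- img + matrix(rnorm(48^2, 0, 0.1), 48)
  # beta-only: the winner is the longest candidate axis
  prm_b <- axis_score_params(alpha = 0, beta = 1, gamma = 0)
  win <- statistical_axis_search(disc, img, prm_b)
  med <- medial_long_axis(disc)
  cs <- candidate_points(disc, med, prm_b)
  lens <- outer(seq_len(nrow(cs$side0)), seq_len(nrow(cs$side1)),
                Vectorize(function(i, j)
                  sqrt(sum((cs$side0[i, ] - cs$side1[j, ])^2))))
  expect_equal(win$length_mm, max(lens))
  # gamma-only on a homogeneous disc: maximal centrality wins
  prm_g <- axis_score_params(alpha = 0, beta = 0, gamma = 1)
  win_g <- statistical_axis_search(disc, img, prm_g)
  expect_equal(centrality_term(attr(win_g, "i"), attr(win_g, "j"), 4), 1)
  expect_error(score_axis(axis_line(c(2, 2), c(2, 2)), 4, 4, disc, img,
                          tl$length_mm, prm), "zero-length")
})

test_that("a two-texture lesion penalises axes that sample one texture", {
  # left half bright, right half dim; a vertical axis inside one half
  # diverges from the whole-lesion distribution, a crossing axis does not
  m <- rect2d(40, 11:30, 11:30)
  img <- matrix(20, 40, 40)
  img[11:30, 11:20] <- 100
  img[11:30, 21:30] <- 60
  set.seed(3); img <- img + matrix(rnorm(1600, 0, 1), 40)
  prm <- axis_score_params()
  su <- list(grid = seq(min(img), max(img), length.out = 256),
             bandwidth = 0.02 * diff(range(img)))
  P <- parzen_pdf(img[m], su$bandwidth, su$grid)
  one_tex <- axis_line(c(12, 15), c(29, 15))   # bright half only
  crossing <- axis_line(c(20, 12), c(20, 29))  # spans both textures
  kl_one <- kl_divergence(P, parzen_pdf(
    bilinear_sample(img, cbind(seq(12, 29, by = 0.25), 15)),
    su$bandwidth, su$grid))
  kl_cross <- kl_divergence(P, parzen_pdf(
    bilinear_sample(img, cbind(20, seq(12, 29, by = 0.25))),
    su$bandwidth, su$grid))
  expect_gt(kl_one, kl_cross)
})

test_that("statistical search agrees with an independent exhaustive scorer", {
  for (seed in c(1, 2, 3)) {
    m <- random_blob2d(seed + 40)
    set.seed(seed)
    img <- matrix(20, nrow(m), ncol(m))
    img[m] <- 90 + rnorm(sum(m), 0, 6)
    img <- img + matrix(rnorm(length(m), 0, 2), nrow(m))
    for (N in c(4L, 8L)) {
      prm <- axis_score_params(N = N, spacing_deg = 8)
      win <- statistical_axis_search(m, img, prm)
      med <- medial_long_axis(m)
      cs <- candidate_points(m, med, prm)
      sc <- oracle_exhaustive_scores(cs, m, img, prm)
      best <- arrayInd(which.max(sc), dim(sc))
      expect_equal(attr(win, "i"), best[1] - 1)
      expect_equal(attr(win, "j"), best[2] - 1)
      expect_equal(attr(win, "score"), max(sc, na.rm = TRUE),
                   tolerance = 1e-8)
    }
  }
})

test_that("sweeping an endpoint never scores below the start axis", {
  eng <- make_engine()
  set.seed(5)
  for (seed in 1:6) {
    m <- random_blob2d(seed + 70)
    img <- matrix(20, nrow(m), ncol(m)); img[m] <- 100
    img <- img + matrix(rnorm(length(m), 0, 3), nrow(m))
    start <- true_longest_axis(m)
    if (start$length_mm == 0) next
    s0 <- eng$segment_2d(img, interaction_input(axes = list(start)))
    swept <- sweep_axis(start, m, img, eng)
    expect_gte(attr(swept, "dsc"), dsc(s0, m) - 1e-12)
  }
})

test_that("sweeping strictly rescues a suboptimal starting drag", {
  # an under-drawn drag whose ROI misses part of an elongated lesion: the
  # swept endpoint slides along the boundary to a position covering it
  m <- ellipse_mask2d(48, c(24, 24), 18, 8)
  img <- matrix(20, 48, 48); img[m] <- 100
  set.seed(8); img <- img + matrix(rnorm(48^2, 0, 2), 48)
  start <- axis_line(c(6, 24), c(24, 16))
  eng <- make_engine()
  s0 <- eng$segment_2d(img, interaction_input(axes = list(start)))
  swept <- sweep_axis(start, m, img, eng,
                      params = axis_score_params(sweep_arc_mm = 25))
  expect_gt(sum(abs(swept$p1 - start$p1)), 0)
  expect_gt(attr(swept, "dsc"), dsc(s0, m))
  # singleton sweep returns the start position
  same <- sweep_axis(start, m, img, eng,
                     params = axis_score_params(sweep_arc_mm = 1e-6))
  expect_lte(sqrt(sum((same$p1 - start$p1)^2)), 1.5)
})
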