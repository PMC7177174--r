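# Shape constructors used across the tests. All deterministic.

disc2d <- function(n, center, r) {
  outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, `+`) <= r^2
}

rect2d <- function(n, rows, cols) {
  m <- matrix(FALSE, n, n)
  m[rows, cols] <- TRUE
  m
}

# digitized ellipse with semi-axes a (row direction), b, rotated by theta_deg
ellipse_mask2d <- function(n, center, a, b, theta_deg = 0) {
  th <- theta_deg * pi / 180
  dr <- outer(seq_len(n) - center[1], rep(1, n))
  dc <- outer(rep(1, n), seq_len(n) - center[2])
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

ball3d <- function(dimv, center, r) {
  dx <- (seq_len(dimv[1]) - center[1])^2
  dy <- (seq_len(dimv[2]) - center[2])^2
  dz <- (seq_len(dimv[3]) - center[3])^2
  array(outer(outer(dx, dy, `+`), dz, `+`) <= r^2, dimv)
}

# random connected 2D blob: union of overlapping discs, deterministic per seed
random_blob2d <- function(seed, n = 48) {
  set.seed(seed)
  k <- sample(2:4, 1)
  c0 <- runif(2, n * 0.35, n * 0.65)
  m <- disc2d(n, c0, runif(1, 4, 9))
  for (i in seq_len(k - 1)) {
    ci <- c0 + runif(2, -7, 7)
    ci <- pmin(pmax(ci, 12), n - 12)
    m <- m | disc2d(n, ci, runif(1, 3, 8))
  }
  lab <- cc_label(m, 8L)
  m & lab == lab[round(c0[1]), round(c0[2])]
}

# simple spherical test phantom: bright sphere on dark noisy background
sphere_phantom <- function(seed = 1, n = 48, r = 12, fg = 100, bg = 20,
                           noise = 2) {
  set.seed(seed)
  gt <- ball3d(rep(n, 3), rep(n / 2, 3), r)
  img <- array(bg, rep(n, 3))
  img[gt] <- fg
  img <- img + array(rnorm(n^3, sd = noise), rep(n, 3))
  list(vol = scalar_volume(img), gt = gt)
}

lesion_from_mask <- function(gt) {
  enumerate_lesions(gt)[[1]]
}
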