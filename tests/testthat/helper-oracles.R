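# Independent brute-force oracles (explicit loops, no reuse of the package's
# search code paths).

# boundary pixels: TRUE pixels 8-adjacent to FALSE or to the image edge
oracle_boundary <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!mask[i, j]) next
    edge <- i == 1 || i == d[1] || j == 1 || j == d[2]
    if (!edge) {
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        if (!mask[i + di, j + dj]) { edge <- TRUE; break }
      }
    }
    if (edge) out <- rbind(out, c(i, j))
  }
  out
}

# longest boundary-pair distance (squared lengths compared exactly)
oracle_longest_len2 <- function(mask) {
  bp <- oracle_boundary(mask)
  best <- 0
  for (i in seq_len(nrow(bp))) for (j in seq_len(nrow(bp))) {
    d2 <- (bp[i, 1] - bp[j, 1])^2 + (bp[i, 2] - bp[j, 2])^2
    if (d2 > best) best <- d2
  }
  best
}

# longest chord at direction theta_deg: boundary pairs whose perpendicular
# offsets differ by at most slab_tol; returns the squared chord length
oracle_chord_len2 <- function(mask, theta_deg, slab_tol = 0.5) {
  bp <- oracle_boundary(mask)
  th <- theta_deg * pi / 180
  v <- c(-sin(th), cos(th))
  best <- -1
  for (i in seq_len(nrow(bp))) for (j in seq_len(nrow(bp))) {
    if (i == j) next
    ds <- abs(sum((bp[i, ] - bp[j, ]) * v))
    d2 <- sum((bp[i, ] - bp[j, ])^2)
    if (ds <= slab_tol && d2 > best) best <- d2
  }
  best
}

# ground-truth boundary point farthest from the segmentation boundary,
# honouring spacing exclusion
oracle_worst_point <- function(seg, gt, existing = NULL, min_spacing = 5,
                               threshold = 2) {
  G <- oracle_boundary(gt)
  S <- oracle_boundary(seg)
  best <- NULL; best_d <- -Inf
  for (i in seq_len(nrow(G))) {
    if (!is.null(existing)) {
      tooclose <- FALSE
      for (k in seq_len(nrow(existing))) {
        if (sqrt(sum((G[i, ] - existing[k, ])^2)) < min_spacing) {
          tooclose <- TRUE; break
        }
      }
      if (tooclose) next
    }
    di <- Inf
    for (j in seq_len(nrow(S)))
      di <- min(di, sqrt(sum((G[i, ] - S[j, ])^2)))
    if (di > best_d) { best_d <- di; best <- G[i, ] }
  }
  if (is.null(best) || best_d < threshold) return(NULL)
  list(point = best, dist = best_d)
}

# direct-summation KL on probability masses with floor smoothing of q
oracle_kl <- function(p, q, kl_floor = 1e-8) {
  p <- p / sum(p)
  q <- q / sum(q) + kl_floor
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i])
  max(0, s)
}

# exact Gaussian-kernel density on a grid, explicit loops
oracle_parzen <- function(samples, bw, grid) {
  dens <- numeric(length(grid))
  for (g in seq_along(grid)) {
    acc <- 0
    for (s in samples)
      acc <- acc + exp(-0.5 * ((grid[g] - s) / bw)^2) / (bw * sqrt(2 * pi))
    dens[g] <- acc / length(samples)
  }
  dx <- grid[2] - grid[1]
  dens / (sum(dens) * dx)
}

# independent scorer for the statistical axis search: given a candidate set,
# evaluates the weighted score (clamped divergence + relative length +
# centrality with the same-side halving rule) for every pair
oracle_exhaustive_scores <- function(cs, mask, img, params) {
  rng <- range(img)
  bw <- params$bandwidth
  if (is.null(bw)) bw <- 0.02 * diff(rng)
  grid <- seq(rng[1], rng[2], length.out = params$n_bins)
  dx <- grid[2] - grid[1]
  P <- oracle_parzen(img[mask], bw, grid)
  # true longest length by brute force
  tl <- sqrt(oracle_longest_len2(mask))
  r <- cs$r
  scores <- matrix(NA_real_, 2 * r + 1, 2 * r + 1)
  for (i in 0:(2 * r)) for (j in 0:(2 * r)) {
    p0 <- cs$side0[i + 1, ]; p1 <- cs$side1[j + 1, ]
    len <- sqrt(sum((p1 - p0)^2))
    if (len <= 0) next
    npts <- max(2, ceiling(len / 0.25) + 1)
    tt <- seq(0, 1, length.out = npts)
    samp <- numeric(npts)
    for (k in seq_len(npts)) {
      pr <- p0[1] + tt[k] * (p1[1] - p0[1])
      pc <- p0[2] + tt[k] * (p1[2] - p0[2])
      r0 <- min(max(floor(pr), 1), nrow(img) - 1)
      c0 <- min(max(floor(pc), 1), ncol(img) - 1)
      fr <- min(max(pr, 1), nrow(img)) - r0
      fc <- min(max(pc, 1), ncol(img)) - c0
      samp[k] <- img[r0, c0] * (1 - fr) * (1 - fc) +
        img[r0 + 1, c0] * fr * (1 - fc) +
        img[r0, c0 + 1] * (1 - fr) * fc +
        img[r0 + 1, c0 + 1] * fr * fc
    }
    Q <- oracle_parzen(samp, bw, grid)
    dkl <- min(1, max(0, oracle_kl(P * dx, Q * dx, params$kl_floor)))
    C <- abs(i - r) + abs(j - r)
    if ((i - r) * (j - r) > 0) C <- C / 2
    centr <- 0.1 + 0.9 * C / (2 * r)
    scores[i + 1, j + 1] <- params$alpha * (1 - dkl) +
      params$beta * (len / tl) + params$gamma * centr
  }
  scores
}
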