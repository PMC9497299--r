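# Independent oracles and small fixtures used across the suite. Everything
# here is deliberately naive (loops, exhaustive enumeration) so that it
# cannot share a defect with the implementation it checks.

small_grid <- function(shape = c(8, 8, 4), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0), direction = diag(3)) {
  image_grid(shape, spacing = spacing, origin = origin, direction = direction)
}

rand_mask <- function(grid, p = 0.2) {
  binary_mask(array(stats::runif(prod(grid$shape)) < p, grid$shape), grid)
}

# boundary by explicit per-voxel neighbour checks
bf_boundary <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!occ[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    on_surface <- FALSE
    for (v in nb) {
      if (any(v < 1) || any(v > d)) { on_surface <- TRUE; break }
      if (!occ[v[1], v[2], v[3]]) { on_surface <- TRUE; break }
    }
    if (on_surface) out <- rbind(out, c(i, j, k))
  }
  out
}

# all-pairs boundary-distance Hausdorff in physical mm
bf_hausdorff <- function(a, b) {
  sp <- a$grid$spacing
  pa <- bf_boundary(a)
  pb <- bf_boundary(b)
  dmat <- matrix(0, nrow(pa), nrow(pb))
  for (u in seq_len(nrow(pa)))
    for (v in seq_len(nrow(pb)))
      dmat[u, v] <- sqrt(sum(((pa[u, ] - pb[v, ]) * sp)^2))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# seeded flood fill over { values >= tau } by repeated frontier expansion
bfs_segment <- function(values, seed_idx, tau, connectivity = 26,
                        region = NULL) {
  d <- dim(values)
  supra <- values >= tau
  if (!is.null(region)) supra <- supra & region
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  seg <- array(FALSE, d)
  if (!supra[seed_idx[1], seed_idx[2], seed_idx[3]]) return(seg)
  seg[seed_idx[1], seed_idx[2], seed_idx[3]] <- TRUE
  frontier <- matrix(seed_idx, nrow = 1)
  while (nrow(frontier) > 0) {
    cand <- NULL
    for (r in seq_len(nrow(offs)))
      cand <- rbind(cand, sweep(frontier, 2, -offs[r, ]))
    keep <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
      cand[, 2] >= 1 & cand[, 2] <= d[2] &
      cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[keep, , drop = FALSE]
    cand <- unique(cand)
    lin <- cand[, 1] + (cand[, 2] - 1) * d[1] + (cand[, 3] - 1) * d[1] * d[2]
    new <- supra[cand] & !seg[cand]
    cand <- cand[new, , drop = FALSE]
    seg[cand] <- TRUE
    frontier <- cand
  }
  seg
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
# (requires no zero differences and no tied |d|, as in wilcox.test's exact
# branch)
enum_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  if (v > n * (n + 1) / 4) p <- mean(vs >= v) else p <- mean(vs <= v)
  min(2 * p, 1)
}

# average ranks (midranks) computed from first principles
midrank <- function(x) {
  sapply(seq_along(x), function(i) sum(x < x[i]) + (1 + sum(x == x[i])) / 2)
}

# Spearman rho as Pearson correlation of midranks, via explicit sums
spearman_oracle <- function(x, y) {
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2)
  syy <- sum((ry - mean(ry))^2)
  sxy / sqrt(sxx * syy)
}

# radial profile of a uniform unit ball of radius R blurred with an
# isotropic Gaussian of sd s (closed form, cross-checked against Monte
# Carlo integration)
blurred_ball_profile <- function(r, R, s) {
  t1 <- stats::pnorm((R - r) / s) - stats::pnorm((-R - r) / s)
  t2 <- (s / (r * sqrt(2 * pi))) *
    (exp(-(r - R)^2 / (2 * s^2)) - exp(-(r + R)^2 / (2 * s^2)))
  t1 - t2
}

# hand-sized unanimous observer set
unanimous_set <- function(grid = small_grid(c(12, 12, 6), c(4, 4, 5)),
                          n_obs = 3) {
  occ <- array(FALSE, grid$shape)
  occ[4:9, 4:9, 2:5] <- TRUE
  m <- binary_mask(occ, grid)
  masks <- rep(list(m), n_obs)
  names(masks) <- paste0("obs", seq_len(n_obs))
  observer_set(masks)
}
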