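# shared fixtures and small oracles, all generated in code

trefoil <- function(n = 120, handedness = 1)
  make_curve("torus_knot", n = n, p = 2, q = 3, handedness = handedness)

fig8 <- function(n = 160) make_curve("figure_eight", n = n)

# uniform random directions through R's RNG (seed set by caller)
rand_dirs <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# brute-force nearest point on the mid-curve by dense grid search
grid_nearest <- function(p, channel, n_grid = 40001) {
  t0 <- p[1] / channel$k
  g <- seq(t0 - 2 * pi, t0 + 2 * pi, length.out = n_grid)
  mc <- midcurve_point(g, channel)
  d2 <- (mc[, 1] - p[1])^2 + (mc[, 2] - p[2])^2 + (mc[, 3] - p[3])^2
  i <- which.min(d2)
  list(t = g[i], distance = sqrt(d2[i]))
}

# relative force-vs-gradient check of the full force field
grad_rel_err <- function(pos, cfg, ..., h = 1e-6) {
  ana <- total_force(pos, cfg, ...)$forces
  num <- pos * 0
  for (i in seq_len(nrow(pos))) for (d in 1:3) {
    pp <- pos; pp[i, d] <- pp[i, d] + h
    pm <- pos; pm[i, d] <- pm[i, d] - h
    num[i, d] <- -(total_force(pp, cfg, ...)$energy -
                     total_force(pm, cfg, ...)$energy) / (2 * h)
  }
  scale <- max(abs(ana), 1)
  max(abs(num - ana)) / scale
}

# random open worm-like chains for writhe-oracle sweeps
random_open_chain <- function(n = 30, seed = 1) {
  make_curve("random_walk", n = n, P = 2, seed = seed)
}
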