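test_that("gyration radii: degenerate cases and Pythagorean decomposition", {
  rod <- cbind(0:9, 0, 0)
  g <- gyration_radii(rod)
  expect_equal(g$R_perp, 0)
  expect_equal(g$R_g, g$R_par)
  expect_equal(gyration_radii(matrix(1, 5, 3))$R_g, 0)
  set.seed(21)
  r <- matrix(rnorm(90), ncol = 3)
  g2 <- gyration_radii(r)
  expect_equal(g2$R_g^2, g2$R_par^2 + g2$R_perp^2, tolerance = 1e-12)
})

test_that("span: rod identity, projection inequality and brute-force oracle", {
  rod <- cbind(0:299, 0, 0)
  expect_equal(chain_span(rod, "axial"), 299)
  expect_equal(chain_span(rod, "euclidean"), 299)
  set.seed(22)
  for (i in 1:10) {
    pts <- matrix(rnorm(45), ncol = 3)
    expect_gte(chain_span(pts, "euclidean"), chain_span(pts, "axial"))
    brute <- max(outer(seq_len(15), seq_len(15), Vectorize(function(a, b)
      sqrt(sum((pts[a, ] - pts[b, ])^2)))))
    expect_equal(chain_span(pts, "euclidean"), brute)
  }
})

test_that("span histogram integrates to one on half-open 1-sigma bins", {
  set.seed(23)
  sp <- runif(5000, 240, 280)
  h <- span_histogram(sp)
  expect_equal(sum(h$P) * attr(h, "binwidth"), 1)
  expect_true(all(h$count >= 0))
  # bin edges anchored at 0: a span of exactly 250 falls in [250, 251)
  h2 <- span_histogram(c(250, 250.999, 251), binwidth = 1)
  expect_equal(h2$count[h2$R == 250.5], 2)
})

test_that("elastic free energy: uniform is flat, Gaussian gives a linear force", {
  u <- span_histogram(rep(seq(100.5, 119.5), each = 50), binwidth = 1)
  a <- elastic_free_energy(u)
  expect_equal(max(abs(a$A)), 0)
  expect_true(all(abs(a$force[!is.na(a$force)]) < 1e-12))
  set.seed(24)
  g <- span_histogram(rnorm(2e5, 150, 5), binwidth = 1)
  af <- elastic_free_energy(g)
  mid <- abs(af$R - 150) < 4
  fit <- lm(af$force[mid] ~ af$R[mid])
  expect_equal(coef(fit)[[2]], -1 / 25, tolerance = 0.1)  # slope -kT/var
  # translation invariance
  g2 <- span_histogram(rnorm(2e5, 150, 5) + 30, binwidth = 1)
  expect_error(elastic_free_energy(span_histogram(rep(1, 10))), "fewer than 2")
})

test_that("radial profiles: cylinder limit and uniform-fill volume check", {
  cfg <- sim_config(N = 50)
  cyl <- helix_channel(D = 8, R_H = 0)
  # fabricated 'trajectory' with uniform random fill of the tube
  set.seed(25)
  n <- 6000
  r <- sqrt(runif(n)) * 4; th <- runif(n, 0, 2 * pi)
  pts <- cbind(runif(n, 0, 50), r * cos(th), r * sin(th))
  tr <- structure(list(frames = array(pts, c(1, n, 3)), times = 0,
                       config = cfg, channel = cyl, seed = 1), class = "trajectory")
  rp <- radial_profiles(tr, cyl)
  expect_equal(rp$midcurve$P, rp$axis$P)  # cylinder: identical references
  expect_equal(sum(rp$midcurve$P), 1)
  # uniform density per volume: P proportional to shell volume
  dens <- rp$axis$P / (rp$axis$shell_volume / sum(rp$axis$shell_volume))
  inner <- rp$axis$r < 3.5
  expect_lt(max(abs(dens[inner] - 1)), 0.25)  # Monte-Carlo tolerance
  # all monomers on the mid-curve -> all mass in the first shell
  hel <- helix_channel(D = 8)
  mc <- midcurve_point(seq(0, 20, length.out = 50), hel)
  tr2 <- structure(list(frames = array(mc, c(1, 50, 3)), times = 0,
                        config = cfg, channel = hel, seed = 1), class = "trajectory")
  rp2 <- radial_profiles(tr2, hel)
  expect_equal(rp2$midcurve$P[1], 1)
})

test_that("confinement free energy counts surface-layer monomers", {
  cfg <- sim_config(N = 20)
  ch <- helix_channel(D = 10, R_H = 0)
  axis_chain <- cbind(seq(0, 19), 0, 0)
  mk <- function(m, reps = 1) structure(list(
    frames = array(rep(t(m), reps), c(reps, nrow(m), 3))[ , , , drop = FALSE],
    times = seq_len(reps), config = cfg, channel = ch, seed = 1), class = "trajectory")
  tr <- structure(list(frames = array(axis_chain, c(1, 20, 3)), times = 0,
                       config = cfg, channel = ch, seed = 1), class = "trajectory")
  expect_equal(confinement_free_energy(tr, ch), 0)
  surf <- cbind(seq(0, 19), 4.95, 0)  # 0.05 inside the wall: within delta = 0.2
  trs <- structure(list(frames = array(surf, c(1, 20, 3)), times = 0,
                        config = cfg, channel = ch, seed = 1), class = "trajectory")
  expect_equal(confinement_free_energy(trs, ch), 20)
  # duplicated frames leave the average unchanged
  tr2 <- structure(list(frames = array(rep(surf, each = 2), c(2, 20, 3)),
                        times = 0:1, config = cfg, channel = ch, seed = 1),
                   class = "trajectory")
  expect_equal(confinement_free_energy(tr2, ch), 20)
})

test_that("orientational correlations: exact limits and WLC decay", {
  rod <- cbind(0:49, 0, 0)
  oc <- orientational_correlation(rod, s_max = 20)
  expect_equal(oc$cos_theta, rep(1, 21))
  expect_equal(oc$cos_theta[oc$s == 0], 1)
  # discrete WLC fixture decays as exp(-s/P)
  wlc <- make_curve("random_walk", n = 3000, P = 20, seed = 31)
  P <- fit_persistence_length(orientational_correlation(wlc, s_max = 60), s_fit = 40)
  expect_equal(P, 20, tolerance = 0.15)
})

test_that("deflection length matches the Odijk scaling values", {
  expect_equal(deflection_length(10, 20), 12.6, tolerance = 0.01)
  expect_equal(deflection_length(20, 20), 20)
  expect_equal(deflection_length(40, 20), 31.7, tolerance = 0.01)
})

test_that("scaling fits recover known constants exactly on synthetic data", {
  DP <- c(0.5, 0.75, 1)
  tabA <- data.frame(DP = DP, R = odijk_span(300, DP, A = 0.1701))
  f <- scaling_fits(span_vs_DP = tabA, L = 300)
  expect_equal(f$A_odijk, 0.1701, tolerance = 1e-10)
  # predicted span at D/P = 0.5: 267.85 sigma
  expect_equal(odijk_span(300, 0.5), 267.85, tolerance = 0.005)
  # noiseless power laws are recovered exactly
  tabDP <- data.frame(DP = c(1, 1.5, 2), R = 100 * c(1, 1.5, 2)^(-1.02))
  expect_equal(scaling_fits(span_vs_DP = tabDP, L = 300)$exponent_DP, -1.02,
               tolerance = 1e-10)
  Fg <- c(2, 5, 10, 20)
  tabF <- data.frame(F = Fg, R = 500 * Fg^(-2.25))
  expect_equal(scaling_fits(span_vs_F = tabF)$exponent_F, -2.25, tolerance = 1e-10)
  expect_error(scaling_fits(span_vs_F = data.frame(F = c(1, 2), R = c(-1, 1))),
               "non-positive")
})

test_that("projection heatmaps: point mass and mirror parity", {
  cfg <- sim_config(N = 5)
  pt <- matrix(rep(c(1.2, 0.7, -0.3), each = 5), ncol = 3)
  tr <- structure(list(frames = array(pt, c(1, 5, 3)), times = 0,
                       config = cfg, channel = NULL, seed = 1), class = "trajectory")
  hm <- projection_heatmap(tr, "yz")
  expect_equal(sum(hm$P), 1)
  expect_equal(max(hm$P), 1)  # single hot bin
})

test_that("running averages converge on stationary series", {
  set.seed(26)
  x <- rnorm(4000, 10)
  ra <- running_average(x)
  expect_lt(abs(tail(ra, 1) - 10), 3 * sd(x) / sqrt(4000) * 2)
})
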