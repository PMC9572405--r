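test_that("bond potential matches the harmonic form and its symmetry", {
  expect_equal(bond_energy_force(1.0)$energy, 0)
  expect_equal(bond_energy_force(1.1, k_s = 80)$energy, 0.8)
  expect_equal(bond_energy_force(0.9, k_s = 80)$energy, 0.8)
  expect_equal(bond_energy_force(1.1, k_s = 80)$force,
               -bond_energy_force(0.9, k_s = 80)$force)
  expect_error(bond_energy_force(0), "non-positive")
})

test_that("bending potential is harmonic in the angle and forces balance", {
  straight <- rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0))
  r <- bend_energy_force(straight, k_b = 20)
  expect_equal(r$energy, 0)
  expect_equal(max(abs(r$forces)), 0)
  # theta = pi - 0.1 with the bare convention prefactor 20 gives 0.2 eps0
  th <- pi - 0.1
  bent <- rbind(c(-1, 0, 0), c(0, 0, 0), c(-cos(th), sin(th), 0))
  r2 <- bend_energy_force(bent, k_b = 20)
  expect_equal(r2$theta, th, tolerance = 1e-12)
  expect_equal(r2$energy, 20 * 0.1^2, tolerance = 1e-12)
  # Newton's third law on random triplets
  set.seed(4)
  for (i in 1:20) {
    tri <- matrix(rnorm(9), 3, 3)
    rr <- bend_energy_force(tri, k_b = 10)
    expect_equal(colSums(rr$forces), c(0, 0, 0), tolerance = 1e-12)
  }
  expect_error(bend_energy_force(rbind(0, 0, 1) %x% t(c(1, 1, 1)) * 0), "coincident")
})

test_that("WCA potential is cut, shifted and continuous", {
  expect_equal(wca_pair_energy_force(2^(1 / 6))$energy, 0)
  expect_equal(wca_pair_energy_force(2^(1 / 6))$force, 0, tolerance = 1e-12)
  expect_equal(wca_pair_energy_force(1.0)$energy, 1.0)
  expect_equal(wca_pair_energy_force(1.5)$energy, 0)
  just_in <- 2^(1 / 6) - 1e-8
  expect_lt(wca_pair_energy_force(just_in)$energy, 1e-6)
  expect_error(wca_pair_energy_force(0), "singularity")
})

test_that("total force is minus the gradient of every potential", {
  set.seed(7)
  cfg <- sim_config(N = 10)
  pos <- cbind(cumsum(c(0, rep(1, 9))), 0, 0) + matrix(rnorm(30, sd = 0.1), ncol = 3)
  expect_lt(grad_rel_err(pos, cfg), 1e-5)
  ch <- helix_channel(D = 4)
  pos2 <- initial_conformation(10, ch) + matrix(rnorm(30, sd = 0.3), ncol = 3)
  expect_lt(grad_rel_err(pos2, cfg, channel = ch, bottom_wall = TRUE,
                         piston_x = 10 + 99.8), 1e-5)
})

test_that("free-chain forces sum to zero and energy is invariant to rigid motions", {
  set.seed(8)
  cfg <- sim_config(N = 20)
  pos <- cbind(cumsum(c(0, rep(1, 19))), 0, 0) + matrix(rnorm(60, sd = 0.15), ncol = 3)
  r <- total_force(pos, cfg)
  expect_equal(colSums(r$forces), c(0, 0, 0), tolerance = 1e-10)
  # translation
  expect_equal(total_force(sweep(pos, 2, c(3, -2, 7), "+"), cfg)$energy,
               r$energy, tolerance = 1e-10)
  # rotation about a random axis
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(total_force(pos %*% t(R), cfg)$energy, r$energy, tolerance = 1e-9)
})

test_that("two non-bonded beads at contact repel along the pair axis", {
  cfg <- sim_config(N = 4, k_b = 1e-9)  # bending switched off
  # beads 1 and 4 at distance 1 with all bonds at their rest length
  pos <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0))
  r <- total_force(pos, cfg)
  f14 <- wca_pair_energy_force(1.0)$force
  expect_gt(f14, 0)
  expect_equal(r$forces[1, 1], -f14, tolerance = 1e-6)
  expect_equal(r$forces[4, 1], f14, tolerance = 1e-6)
})

test_that("neighbour-list integration matches the all-pairs force evaluation", {
  # one Langevin step with gamma = 0 from a compact conformation must move
  # beads exactly as the all-pairs forces dictate
  set.seed(11)
  cfg <- sim_config(N = 24, gamma = 0)
  pos <- make_curve("random_walk", n = 24, P = 3, seed = 5) * 0.8
  vel <- matrix(0, 24, 3)
  step <- langevin_step(pos, vel, cfg)
  f <- total_force(pos, cfg)$forces
  # BAOAB with gamma=0: x' = x + dt*v + (dt^2/2) F(x)
  expect_equal(step$positions, pos + cfg$dt^2 / 2 * f, tolerance = 1e-12)
})
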