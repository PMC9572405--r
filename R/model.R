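#' Harmonic bond energy and force
#'
#' \eqn{U_s(r) = k_s (r - r_0)^2}; the scalar force is \eqn{-dU/dr},
#' applied along the bond.
#'
#' @param r inter-bead distance, \eqn{\sigma} (must be > 0).
#' @param k_s bond stiffness, \eqn{\epsilon_0/\sigma^2}.
#' @param r0 equilibrium bond length, \eqn{\sigma}.
#' @return list with `energy` and scalar `force` (\eqn{-dU/dr}).
#' @export
bond_energy_force <- function(r, k_s = 80, r0 = 1) {
  if (any(r <= 0)) stop("invalid geometry: non-positive bond length")
  list(energy = k_s * (r - r0)^2, force = -2 * k_s * (r - r0))
}

#' Harmonic bending energy and bead-triplet forces
#'
#' \eqn{U_b(\theta) = c (\theta - \theta_0)^2} at the interior bead of a
#' triplet, with \eqn{\theta_0 = \pi} (straight). The prefactor `c` is
#' passed directly; use [bend_prefactor][sim_config()] conventions via the
#' config when integrating. Forces on the three beads sum to zero.
#'
#' @param triplet 3 x 3 matrix of bead positions (rows: i-1, i, i+1).
#' @param k_b bending prefactor `c`, \eqn{\epsilon_0/\mathrm{rad}^2}.
#' @param theta0 equilibrium angle (radians).
#' @return list with `energy`, `theta` and 3 x 3 `forces`.
#' @export
bend_energy_force <- function(triplet, k_b = 10, theta0 = pi) {
  stopifnot(is.matrix(triplet), nrow(triplet) == 3, ncol(triplet) == 3)
  a <- triplet[1, ] - triplet[2, ]
  b <- triplet[3, ] - triplet[2, ]
  la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2))
  if (la == 0 || lb == 0) stop("invalid geometry: coincident beads in triplet")
  cth <- max(-1, min(1, sum(a * b) / (la * lb)))
  theta <- acos(cth)
  dth <- theta - theta0
  sth <- sqrt(1 - cth^2)
  wc <- if (sth > 1e-9) 2 * k_b * dth / sth else -2 * k_b
  ua <- a / la; ub <- b / lb
  f1 <- (wc / la) * (ub - cth * ua)
  f3 <- (wc / lb) * (ua - cth * ub)
  forces <- rbind(f1, -(f1 + f3), f3)
  rownames(forces) <- NULL
  list(energy = k_b * dth^2, theta = theta, forces = forces)
}

#' WCA pair energy and force
#'
#' Fully repulsive truncated-and-shifted Lennard-Jones excluded volume:
#' \eqn{U(r) = 4\epsilon_0[(\sigma/r)^{12} - (\sigma/r)^6 + 1/4]} for
#' \eqn{r < 2^{1/6}\sigma}, 0 beyond; the force is continuous (zero) at the
#' cutoff.
#'
#' @param r pair distance, \eqn{\sigma} (> 0).
#' @param sigma interaction length scale.
#' @return list with `energy` and scalar `force` (\eqn{-dU/dr}).
#' @export
wca_pair_energy_force <- function(r, sigma = 1) {
  if (any(r == 0)) stop("singularity: zero pair distance")
  if (any(r < 0)) stop("invalid geometry: negative pair distance")
  cut <- 2^(1 / 6) * sigma
  s6 <- (sigma / r)^6
  e <- ifelse(r < cut, 4 * (s6^2 - s6) + 1, 0)
  f <- ifelse(r < cut, 24 * (2 * s6^2 - s6) / r, 0)
  list(energy = e, force = f)
}

#' Total per-bead force and potential energy of a conformation
#'
#' Sums harmonic bonds, harmonic bending, WCA excluded volume over all pairs
#' except directly bonded neighbours, the implicit channel wall, the bottom
#' wall and the piston (each only if supplied). For a free chain the forces
#' sum to zero.
#'
#' @param positions N x 3 matrix of bead positions.
#' @param config a [sim_config()].
#' @param channel optional [helix_channel()].
#' @param bottom_wall logical; impenetrable wall at x = 0.
#' @param piston_x optional piston centre x-coordinate (piston of radius
#'   100 sigma, WCA contact offset 99.5 sigma).
#' @return list with `forces` (N x 3), `energy`, and `piston_reaction`
#'   (x-force of the chain on the piston).
#' @export
total_force <- function(positions, config, channel = NULL,
                        bottom_wall = FALSE, piston_x = NULL) {
  stopifnot(is.matrix(positions), ncol(positions) == 3)
  if (any(!is.finite(positions))) stop("non-finite coordinates")
  ch_on <- !is.null(channel)
  forces_cpp(positions, config$k_s, config$r0, bend_prefactor(config),
             ch_on,
             if (ch_on) channel$R_ch else 1, if (ch_on) channel$R_H else 0,
             if (ch_on) channel$k else 1, if (ch_on) channel$omega else 1,
             bottom_wall, !is.null(piston_x),
             if (is.null(piston_x)) 0 else piston_x, 99.5)
}
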