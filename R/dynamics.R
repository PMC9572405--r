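#' Initial conformation: straight chain along the channel axis
#'
#' Beads at 1-sigma spacing in a straight line on the channel x-axis,
#' starting at `x0`. The axis lies inside the helical tube whenever
#' \eqn{R_H < R_{ch} - } the wall cutoff (always true for the standard
#' \eqn{R_H = R_{ch}/3} geometries), so the start is wall-violation-free
#' at any confinement strength; if the axis would touch the wall the chain
#' is laid along the mid-curve instead (`mode = "midcurve"` forces this).
#'
#' @param N bead count.
#' @param channel optional [helix_channel()]; `NULL` gives a straight rod
#'   on the x-axis.
#' @param x0 x-coordinate of the first bead.
#' @param spacing bond length of the initial chain.
#' @param mode `"axis"` or `"midcurve"`.
#' @return N x 3 position matrix.
#' @export
initial_conformation <- function(N, channel = NULL, x0 = 1, spacing = 1,
                                 mode = c("axis", "midcurve")) {
  mode <- match.arg(mode)
  wall_cut <- 2^(1 / 6) * 0.5
  axis_ok <- is.null(channel) ||
    (channel$R_H < channel$R_ch - wall_cut - 0.05)
  if (mode == "axis" && axis_ok)
    return(cbind(x0 + spacing * (seq_len(N) - 1), 0, 0))
  # chord |r0(t + dt) - r0(t)| = spacing along the helix mid-curve
  if (channel$R_H == 0)
    return(cbind(x0 + spacing * (seq_len(N) - 1), 0, 0))
  chord <- function(dt) sqrt((channel$k * dt)^2 +
                               (2 * channel$R_H * sin(dt / 2))^2) - spacing
  dt <- stats::uniroot(chord, c(1e-8, 2 * pi), tol = 1e-14)$root
  t <- x0 / channel$k + dt * (seq_len(N) - 1)
  midcurve_point(t, channel)
}

#' One (or a few) Langevin BAOAB steps
#'
#' Advances the chain with the BAOAB splitting of the Langevin equation
#' \eqn{m\ddot r = -\gamma m\dot r - \nabla U + R(t)(2\epsilon_0 m\gamma)^{1/2}}
#' at `config$dt`. With `gamma = 0` the scheme reduces to velocity Verlet
#' (no noise drawn). Deterministic given the R RNG state.
#'
#' @param positions,velocities N x 3 matrices.
#' @param config a [sim_config()].
#' @param channel optional [helix_channel()].
#' @param n_steps number of steps to take.
#' @param bottom_wall,piston_x,piston_force,mirror_noise see
#'   [run_simulation()].
#' @return list with `positions`, `velocities`, `piston_x`.
#' @export
langevin_step <- function(positions, velocities, config, channel = NULL,
                          n_steps = 1L, bottom_wall = FALSE,
                          piston_x = NULL, piston_force = 0,
                          mirror_noise = FALSE) {
  ch_on <- !is.null(channel)
  res <- run_md_cpp(positions, velocities,
                    config$k_s, config$r0, bend_prefactor(config),
                    config$gamma, config$dt, n_steps, 0L,
                    ch_on,
                    if (ch_on) channel$R_ch else 1, if (ch_on) channel$R_H else 0,
                    if (ch_on) channel$k else 1, if (ch_on) channel$omega else 1,
                    bottom_wall,
                    !is.null(piston_x), if (is.null(piston_x)) 0 else piston_x,
                    piston_force, 200 * config$gamma, 99.5,
                    0.8, mirror_noise, TRUE, FALSE)
  list(positions = res$pos, velocities = res$vel,
       piston_x = if (is.null(piston_x)) NULL else res$piston_final)
}

#' One overdamped piston step
#'
#' The piston (radius 100 sigma, centre constrained to the channel axis)
#' obeys overdamped 1-D Langevin dynamics: drift from the applied force
#' \eqn{-F} (toward the bottom wall) plus the chain's WCA reaction, with
#' friction `gamma_p` (default 200x the bead friction, the piston/bead
#' radius ratio) and thermal noise at \eqn{k_BT = \epsilon_0}.
#'
#' @param piston_x current piston centre x.
#' @param chain_force_x x-force exerted by the chain on the piston.
#' @param F applied compressive force, \eqn{\epsilon_0/\sigma}.
#' @param config a [sim_config()].
#' @param gamma_p piston friction; default `200 * config$gamma`.
#' @param thermostat draw the thermal kick? (`FALSE` = quasi-static).
#' @return updated piston x (clamped at the bottom-wall contact).
#' @export
piston_update <- function(piston_x, chain_force_x, F, config,
                          gamma_p = 200 * config$gamma, thermostat = TRUE) {
  stopifnot(F >= 0)
  dt <- config$dt
  x <- piston_x + dt * (-F + chain_force_x) / gamma_p +
    if (thermostat) sqrt(2 * dt / gamma_p) * rnorm(1) else 0
  max(x, 99.5)
}

new_trajectory <- function(frames, times, piston_x, config, channel, seed,
                           velocities = NULL) {
  structure(list(frames = frames, times = times, piston_x = piston_x,
                 velocities = velocities,
                 config = config, channel = channel, seed = seed,
                 config_hash = config_hash(config)),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) if (length(traj$frames)) dim(traj$frames)[1] else 0L

#' Extract one frame as an N x 3 matrix
#' @param traj a `trajectory`.
#' @param i frame index.
#' @return N x 3 position matrix.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$frames[i, , ], ncol = 3)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d beads, t in [%g, %g] tau, seed %d, config %s\n",
              n_frames(x), x$config$N,
              if (n_frames(x)) min(x$times) else NA,
              if (n_frames(x)) max(x$times) else NA,
              x$seed, x$config_hash))
  invisible(x)
}

#' Run a confined-chain Langevin simulation
#'
#' Full protocol: the chain is initialized extended along the channel
#' mid-curve near the bottom wall, an optional piston of radius 100 sigma
#' is placed beyond the far chain end and driven toward the bottom wall
#' with force `F`, a pre-equilibration run is discarded, and production
#' frames are sampled uniformly.
#'
#' @param config a [sim_config()].
#' @param channel optional [helix_channel()]; `NULL` simulates a free chain.
#' @param protocol list with `pre_equilibration_steps`,
#'   `production_steps`, `sample_interval`, `force` (compressive force
#'   \eqn{F\sigma/\epsilon_0}, 0 disables the piston unless
#'   `piston = TRUE`), `piston` (logical or `NULL`), `bottom_wall`
#'   (default: on when the piston is on), `n_repeats`.
#' @param seed integer seed; repeats use `seed`, `seed + 1`, ....
#' @param mirror_noise negate the z-component of the thermal noise stream
#'   (used for exact mirror-equivariance checks).
#' @param store_velocities keep per-frame velocities.
#' @return a `trajectory`, or a list of them if `n_repeats > 1`.
#' @export
run_simulation <- function(config, channel = NULL, protocol = list(),
                           seed = config$seed, mirror_noise = FALSE,
                           store_velocities = FALSE) {
  proto <- modifyList(list(pre_equilibration_steps = 0,
                           production_steps = config$n_steps,
                           sample_interval = config$sample_interval,
                           force = 0, piston = NULL, bottom_wall = NULL,
                           init = "extended", n_repeats = 1L), protocol)
  if (proto$n_repeats > 1) {
    return(lapply(seq_len(proto$n_repeats) - 1L, function(k) {
      p2 <- proto; p2$n_repeats <- 1L
      run_simulation(config, channel, p2, seed = seed + k,
                     mirror_noise = mirror_noise,
                     store_velocities = store_velocities)
    }))
  }
  stopifnot(proto$force >= 0)
  piston_on <- isTRUE(proto$piston) || (is.null(proto$piston) && proto$force > 0)
  bottom_wall <- if (is.null(proto$bottom_wall)) piston_on else proto$bottom_wall

  set.seed(seed)
  # "extended": straight along the mid-curve (safe inside any channel).
  # "wlc": an equilibrium draw of the bending degrees of freedom -- only
  # meaningful for free chains, where it removes the long equilibration of
  # long-wavelength tangent decorrelation.
  pos <- if (identical(proto$init, "wlc")) {
    if (!is.null(channel)) stop("init = 'wlc' is only available for free chains")
    # offset seed: the fixture RNG namespace stays disjoint from the
    # velocity/thermostat stream seeded above.  The walk ignores excluded
    # volume, so redraw (deterministically) until no non-bonded pair
    # overlaps hard enough to destabilize the first steps.
    w <- NULL
    for (attempt in 0:49) {
      w <- make_curve("random_walk", n = config$N, P = config$P,
                      seed = seed + 483647L + attempt * 10007L)
      dm <- as.matrix(stats::dist(w))
      dm[abs(row(dm) - col(dm)) <= 1] <- Inf
      if (min(dm) > 0.95) break
      w <- NULL
    }
    if (is.null(w)) stop("could not draw an overlap-free WLC start")
    w
  } else {
    initial_conformation(config$N, channel, x0 = if (bottom_wall) 1 else 0)
  }
  vel <- matrix(rnorm(3 * config$N), ncol = 3)  # Maxwell-Boltzmann at kT = 1
  # With mirror_noise the initial velocities and every thermal kick have
  # their z-components negated; the initial positions need no flip because
  # initial_conformation() of the -omega channel is already the mirror image
  # of the +omega one.
  if (mirror_noise) vel[, 3] <- -vel[, 3]
  # piston surface just beyond the WCA cutoff from the far chain end
  piston_x <- max(pos[, 1]) + 99.5 + 1.5
  ch_on <- !is.null(channel)
  args_fixed <- list(config$k_s, config$r0, bend_prefactor(config),
                     config$gamma, config$dt)
  run1 <- function(p, v, px, nsteps, sample_every) {
    run_md_cpp(p, v, args_fixed[[1]], args_fixed[[2]], args_fixed[[3]],
               args_fixed[[4]], args_fixed[[5]], nsteps, sample_every,
               ch_on,
               if (ch_on) channel$R_ch else 1, if (ch_on) channel$R_H else 0,
               if (ch_on) channel$k else 1, if (ch_on) channel$omega else 1,
               bottom_wall, piston_on, px, proto$force,
               200 * config$gamma, 99.5, 0.8, mirror_noise, TRUE,
               store_velocities)
  }
  if (proto$pre_equilibration_steps > 0) {
    pre <- run1(pos, vel, piston_x, proto$pre_equilibration_steps, 0L)
    pos <- pre$pos; vel <- pre$vel; piston_x <- pre$piston_final
  }
  if (proto$production_steps > 0) {
    prod <- run1(pos, vel, piston_x, proto$production_steps,
                 proto$sample_interval)
    frames <- prod$frames
    times <- proto$pre_equilibration_steps * config$dt + prod$times
    new_trajectory(frames, times,
                   if (piston_on) prod$piston_x else NULL,
                   config, channel, seed,
                   velocities = if (store_velocities) prod$vframes else NULL)
  } else {
    # zero-step protocol: the initial conformation, unchanged
    frames <- array(pos, dim = c(1, config$N, 3))
    new_trajectory(frames, 0, if (piston_on) piston_x else NULL,
                   config, channel, seed)
  }
}

#' Mirror a conformation or trajectory through the z = 0 plane
#'
#' The mirror image of a `+omega` helical channel is the `-omega` channel;
#' reflecting positions (and the noise stream) through z = 0 therefore maps
#' a simulation in one channel onto its mirror twin exactly.
#'
#' @param x an N x 3 matrix or a `trajectory`.
#' @return the mirrored object.
#' @export
mirror_z <- function(x) {
  if (inherits(x, "trajectory")) {
    x$frames[, , 3] <- -x$frames[, , 3]
    if (!is.null(x$channel)) x$channel$omega <- -x$channel$omega
    return(x)
  }
  x[, 3] <- -x[, 3]
  x
}
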