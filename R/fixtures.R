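#' Deterministic parametric test curves
#'
#' Families: `"circle"`, `"torus_knot"` (requires coprime `p`, `q`;
#' `(2,3)` is the trefoil), `"figure_eight"`, `"random_walk"` (a discrete
#' worm-like chain with persistence length `P`, open), `"rod"` (open
#' straight line). `handedness = -1` returns the exact z-mirror of the
#' `+1` curve. The fixture RNG (for `random_walk`) is seeded locally so it
#' never perturbs simulation RNG streams.
#'
#' @param family curve family.
#' @param n number of vertices (torus knots need `n >= 3 p q` for a
#'   faithful discretization).
#' @param p,q torus-knot winding numbers.
#' @param P persistence length of the random walk (sigma).
#' @param handedness +1 or -1 (z-mirror).
#' @param seed seed for the random-walk family.
#' @return n x 3 vertex matrix; closed families carry class
#'   `closed_curve`.
#' @export
make_curve <- function(family = c("circle", "torus_knot", "figure_eight",
                                  "random_walk", "rod"),
                       n = 200, p = 2, q = 3, P = 20, handedness = 1,
                       seed = 42) {
  family <- match.arg(family)
  stopifnot(handedness %in% c(-1, 1), n >= 3)
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  v <- switch(family,
    circle = cbind(cos(t), sin(t), 0 * t),
    torus_knot = {
      if (p < 1 || q < 1 || gcd_int(p, q) != 1)
        stop("torus knot requires coprime p, q >= 1")
      if (n < 3 * p * q)
        stop("torus_knot needs n >= 3*p*q vertices for a faithful discretization")
      # minus sign makes handedness = +1 the right-handed knot (positive writhe)
      cbind((2 + cos(q * t)) * cos(p * t),
            (2 + cos(q * t)) * sin(p * t),
            -sin(q * t))
    },
    figure_eight = cbind((2 + cos(2 * t)) * cos(3 * t),
                         (2 + cos(2 * t)) * sin(3 * t),
                         sin(4 * t)),
    random_walk = {
      withr_seed <- .Random.seed_exists()
      on.exit(restore_seed(withr_seed), add = TRUE)
      set.seed(seed)
      tang <- matrix(0, n - 1, 3)
      tang[1, ] <- c(1, 0, 0)
      for (i in 2:(n - 1)) tang[i, ] <- rotate_tangent(tang[i - 1, ], P)
      rbind(0, apply(tang, 2, cumsum))
    },
    rod = cbind(seq(0, n - 1), 0 * t, 0 * t))
  if (handedness == -1) v[, 3] <- -v[, 3]
  if (family %in% c("circle", "torus_knot", "figure_eight"))
    closed_curve(v, provenance = family)
  else v
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_seed <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

# one WLC step: polar deviation from the equilibrium of U = (P/2) theta^2
# with the small-angle measure sin(theta) dtheta, i.e. Rayleigh(1/sqrt(P));
# <theta^2> = 2/P so <cos theta> ~ 1 - 1/P and the walk has persistence P
rotate_tangent <- function(u, P) {
  th <- sqrt(-2 * log(runif(1))) / sqrt(P)
  ph <- runif(1, 0, 2 * pi)
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3], a[1] * u[2] - a[2] * u[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3], u[1] * e1[2] - u[2] * e1[1])
  v <- cos(th) * u + sin(th) * (cos(ph) * e1 + sin(ph) * e2)
  v / sqrt(sum(v^2))
}

#' Seeded end-to-end mini-simulation for integration tests
#'
#' A small chain (default N = 10) run briefly through the full
#' [run_simulation()] machinery; bitwise reproducible given the seed.
#'
#' @param config_overrides named list of [sim_config()] arguments.
#' @param channel optional [helix_channel()].
#' @param protocol_overrides named list merged into a short default
#'   protocol (1000 steps, sample every 100).
#' @param seed integer seed.
#' @param ... passed to [run_simulation()].
#' @return a `trajectory`.
#' @export
make_micro_trajectory <- function(config_overrides = list(), channel = NULL,
                                  protocol_overrides = list(), seed = 1L, ...) {
  cfg <- do.call(sim_config, modifyList(list(N = 10L), config_overrides))
  proto <- modifyList(list(pre_equilibration_steps = 0,
                           production_steps = 1000, sample_interval = 100),
                      protocol_overrides)
  run_simulation(cfg, channel, proto, seed = seed, ...)
}
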