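#' Simulation configuration
#'
#' Collects every reduced-unit parameter of the chain model and integration
#' protocol. Defaults reproduce the standard study conditions: a 300-bead
#' chain (2.55 kbp at 8.5 bp per bead), harmonic bonds
#' \eqn{U_s = k_s (r - r_0)^2} with \eqn{k_s = 80\,\epsilon_0/\sigma^2},
#' harmonic bending about \eqn{\theta_0 = \pi} calibrated to a persistence
#' length of \eqn{P = 20\,\sigma} (50 nm), fully repulsive WCA excluded
#' volume, and a BAOAB Langevin integrator at \eqn{d\tau = 0.01\,\tau}.
#'
#' @param N bead count (>= 3).
#' @param k_s bond stiffness, \eqn{\epsilon_0/\sigma^2}.
#' @param r0 equilibrium bond length, \eqn{\sigma}.
#' @param k_b bending constant, \eqn{\epsilon_0/\mathrm{rad}^2}.
#' @param bend_convention `"half"` applies \eqn{U_b = (k_b/2)(\theta-\pi)^2}
#'   (the engine convention, giving \eqn{P \approx k_b \sigma}); `"bare"`
#'   applies the literal \eqn{U_b = k_b (\theta-\pi)^2}.
#' @param P target persistence length in \eqn{\sigma} (metadata; the
#'   realized value is set by `k_b` and `bend_convention`).
#' @param gamma bead friction, \eqn{1/\tau}.
#' @param dt integration time step, \eqn{\tau}.
#' @param n_steps,sample_interval production length and sampling stride.
#' @param seed integer RNG seed.
#' @param sigma_nm,bp_per_bead,tau_ns physical-unit mapping (metadata only).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(N = 300L, k_s = 80, r0 = 1, k_b = 20,
                       bend_convention = c("half", "bare"),
                       P = 20, gamma = 1, dt = 0.01,
                       n_steps = 1e6, sample_interval = 1000L,
                       seed = 1L,
                       sigma_nm = 2.5, bp_per_bead = 8.5, tau_ns = 74) {
  bend_convention <- match.arg(bend_convention)
  stopifnot(N >= 3, k_s > 0, k_b > 0, gamma >= 0, dt > 0, r0 > 0,
            n_steps >= 0, sample_interval >= 1)
  cfg <- list(N = as.integer(N), k_s = k_s, r0 = r0, k_b = k_b,
              bend_convention = bend_convention, theta0 = pi, P = P,
              gamma = gamma, dt = dt, n_steps = n_steps,
              sample_interval = as.integer(sample_interval),
              seed = as.integer(seed),
              sigma_nm = sigma_nm, bp_per_bead = bp_per_bead, tau_ns = tau_ns)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> N = %d beads (%.2f kbp), k_s = %g, k_b = %g (%s), P = %g sigma\n",
              x$N, x$N * x$bp_per_bead / 1000, x$k_s, x$k_b,
              x$bend_convention, x$P))
  cat(sprintf("  dt = %g tau, gamma = %g/tau, n_steps = %g, sample every %d, seed %d\n",
              x$dt, x$gamma, x$n_steps, x$sample_interval, x$seed))
  invisible(x)
}

#' Effective bending prefactor c in U_b = c (theta - pi)^2
#' @noRd
bend_prefactor <- function(config) {
  if (config$bend_convention == "half") config$k_b / 2 else config$k_b
}

#' Helical (or cylindrical) confining channel
#'
#' Geometry of the implicit confining tube. The mid-curve is the helix
#' \eqn{r_0(t) = (k t,\ R_H \cos\omega t,\ R_H \sin\omega t)} with the
#' channel axis along x and an optional impenetrable bottom wall at x = 0.
#' `R_H = 0` gives a straight cylinder. Defaults follow the study geometry:
#' \eqn{R_H = R_{ch}/3} and pitch parameter \eqn{k = D/2\pi} so that the
#' loop spacing \eqn{d_H = 2\pi k} equals the diameter \eqn{D = 2 R_{ch}}.
#'
#' @param D channel diameter in \eqn{\sigma} (`D = 2 R_ch`).
#' @param R_H helix radius; default `R_ch / 3`. Use 0 for a cylinder.
#' @param pitch pitch parameter k in \eqn{\sigma}/rad; default `D / (2*pi)`.
#' @param omega handedness, +1 or -1.
#' @param L_ch channel length in \eqn{\sigma} (used by analyses that
#'   normalize per channel volume).
#' @return An object of class `helix_channel`.
#' @export
helix_channel <- function(D, R_H = D / 6, pitch = D / (2 * pi),
                          omega = 1, L_ch = 2 * D * pi) {
  stopifnot(D > 0, pitch > 0)
  R_ch <- D / 2
  if (!omega %in% c(-1, 1)) stop("omega must be +1 or -1")
  if (R_H < 0 || R_H >= R_ch)
    stop("invariant violated: R_H must satisfy 0 <= R_H < R_ch")
  if (2 * pi * pitch <= R_ch)
    stop("invariant violated: 2*pi*pitch > R_ch is required for a unique nearest point")
  ch <- list(R_ch = R_ch, D = D, R_H = R_H, k = pitch,
             d_H = 2 * pi * pitch, omega = omega, L_ch = L_ch)
  class(ch) <- "helix_channel"
  ch
}

#' @export
print.helix_channel <- function(x, ...) {
  kind <- if (x$R_H == 0) "cylinder" else
    sprintf("helix (R_H = %.3g, omega = %+d)", x$R_H, x$omega)
  cat(sprintf("<helix_channel> D = %g sigma, %s, pitch k = %.4g (d_H = %.4g sigma)\n",
              x$D, kind, x$k, x$d_H))
  invisible(x)
}

.config_keys <- c("N", "k_s", "r0", "k_b", "bend_convention", "P", "gamma",
                  "dt", "n_steps", "sample_interval", "seed",
                  "sigma_nm", "bp_per_bead", "tau_ns")
.channel_keys <- c("D", "R_H", "R_H_fraction", "pitch", "omega", "L_ch")
.protocol_keys <- c("pre_equilibration_steps", "production_steps",
                    "sample_interval", "n_repeats", "force", "piston")

#' Load a simulation configuration from a YAML file
#'
#' The file holds flat keys named as in [sim_config()], an optional
#' `channel:` block named as in [helix_channel()] (`R_H_fraction` may be
#' given instead of `R_H`), and an optional `protocol:` block
#' (`pre_equilibration_steps`, `production_steps`, `sample_interval`,
#' `n_repeats`, `force`, `piston`). Unknown keys are rejected.
#'
#' @param path path to a YAML file.
#' @return A list with elements `config`, `channel` (may be `NULL`) and
#'   `protocol`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 resolves a bare key `N` to a boolean; map it back (it is the
  # only schema key affected)
  names(raw)[names(raw) == "FALSE"] <- "N"
  ch_raw <- raw$channel; raw$channel <- NULL
  pr_raw <- raw$protocol; raw$protocol <- NULL
  bad <- setdiff(names(raw), .config_keys)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- do.call(sim_config, raw)
  channel <- NULL
  if (!is.null(ch_raw)) {
    bad <- setdiff(names(ch_raw), .channel_keys)
    if (length(bad)) stop("unknown channel keys: ", paste(bad, collapse = ", "))
    if (!is.null(ch_raw$R_H_fraction)) {
      ch_raw$R_H <- ch_raw$R_H_fraction * ch_raw$D / 2
      ch_raw$R_H_fraction <- NULL
    }
    channel <- do.call(helix_channel, ch_raw)
  }
  protocol <- list(pre_equilibration_steps = 0, production_steps = cfg$n_steps,
                   sample_interval = cfg$sample_interval, n_repeats = 1L,
                   force = 0, piston = NULL)
  if (!is.null(pr_raw)) {
    bad <- setdiff(names(pr_raw), .protocol_keys)
    if (length(bad)) stop("unknown protocol keys: ", paste(bad, collapse = ", "))
    protocol <- modifyList(protocol, pr_raw)
  }
  list(config = cfg, channel = channel, protocol = protocol)
}

#' Stable short hash of a configuration (FNV-1a over its canonical string)
#' @param config a `sim_config` (or any list of atomic fields).
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(v)
    paste(format(v, digits = 17), collapse = ","), ""), sep = "=", collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
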