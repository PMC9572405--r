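#' Point on the channel mid-curve
#'
#' \eqn{r_0(t) = (k t,\ R_H\cos\omega t,\ R_H\sin\omega t)}. For
#' `R_H = 0` this is the channel axis (the x-axis).
#'
#' @param t mid-curve parameter (radians), vectorized.
#' @param channel a [helix_channel()].
#' @return length(t) x 3 matrix of points.
#' @export
midcurve_point <- function(t, channel) {
  cbind(channel$k * t,
        channel$R_H * cos(channel$omega * t),
        channel$R_H * sin(channel$omega * t))
}

#' Stationarity residual of the nearest-point problem
#'
#' The derivative condition of minimizing \eqn{|p - r_0(t)|^2}:
#' \eqn{g(t) = k(x - kt) - R_H\,\omega\,(y\sin\omega t - z\cos\omega t)}
#' (the \eqn{R_H^2} cross terms cancel). \eqn{g(t^*) = 0} at the nearest
#' mid-curve point.
#'
#' @param t mid-curve parameter (vectorized).
#' @param p 3-vector, the query point.
#' @param channel a [helix_channel()].
#' @return residual values g(t).
#' @export
stationarity_residual <- function(t, p, channel) {
  w <- channel$omega
  channel$k * (p[1] - channel$k * t) -
    channel$R_H * w * (p[2] * sin(w * t) - p[3] * cos(w * t))
}

#' Nearest mid-curve point, distance and outward normal
#'
#' Newton iteration on the stationarity residual from the axial-projection
#' initial guess \eqn{t_0 = x/k}, with a bisection fallback over one pitch;
#' exact closed form for the cylinder (`R_H = 0`). Uniqueness holds for
#' points inside the tube when \eqn{2\pi k > R_{ch}}; exterior queries are
#' solved but flagged.
#'
#' @param p a 3-vector or an N x 3 matrix of query points.
#' @param channel a [helix_channel()].
#' @return for a single point, a list with `t`, `point`, `distance`,
#'   `normal`, `outside`; for a matrix, a data.frame with columns `t`,
#'   `distance`, `nx`, `ny`, `nz`, `outside`.
#' @export
nearest_helix_point <- function(p, channel) {
  single <- !is.matrix(p)
  pts <- if (single) matrix(p, 1, 3) else p
  res <- helix_nearest_cpp(pts, channel$R_ch, channel$R_H, channel$k, channel$omega)
  if (any(res[, 6] != 0))
    stop("helix nearest-point solver failed to converge")
  outside <- res[, 2] > channel$R_ch
  if (single) {
    list(t = res[1, 1], point = drop(midcurve_point(res[1, 1], channel)),
         distance = res[1, 2], normal = res[1, 3:5], outside = outside[1])
  } else {
    data.frame(t = res[, 1], distance = res[, 2],
               nx = res[, 3], ny = res[, 4], nz = res[, 5], outside = outside)
  }
}

#' Implicit wall repulsion on a bead
#'
#' WCA-form repulsion acting on the surface gap \eqn{g_w = R_{ch} - d}
#' with length scale \eqn{\sigma/2} (the bead radius): active for
#' \eqn{g_w < 2^{1/6}\sigma/2}, directed along the inward normal (toward
#' the mid-curve), zero deep inside the channel.
#'
#' @param p bead centre (3-vector).
#' @param channel a [helix_channel()].
#' @param bead_radius wall interaction length scale (default 0.5).
#' @return list with `force` (3-vector), `energy`, `gap`.
#' @export
wall_force <- function(p, channel, bead_radius = 0.5) {
  np <- nearest_helix_point(p, channel)
  gap <- channel$R_ch - np$distance
  if (gap <= 0)
    stop("bead outside the channel wall (distance ", signif(np$distance, 6),
         " > R_ch = ", channel$R_ch, ")")
  cut <- 2^(1 / 6) * bead_radius
  if (gap >= cut) return(list(force = c(0, 0, 0), energy = 0, gap = gap))
  wca <- wca_pair_energy_force(gap, sigma = bead_radius)
  # -dU/dg along -normal: pushes the bead toward the mid-curve
  list(force = -wca$force * np$normal, energy = wca$energy, gap = gap)
}
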