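#' Radius of gyration and its transverse component
#'
#' \eqn{R_g} is the root-mean-square bead distance from the centroid;
#' \eqn{R_\perp} uses only the two transverse coordinates (y, z) relative
#' to the channel axis (x). The second-moment decomposition
#' \eqn{R_g^2 = R_\parallel^2 + R_\perp^2} holds exactly.
#'
#' @param positions N x 3 matrix.
#' @return list with `R_g`, `R_perp`, `R_par`.
#' @export
gyration_radii <- function(positions) {
  stopifnot(is.matrix(positions), ncol(positions) == 3, nrow(positions) >= 2)
  c0 <- colMeans(positions)
  d2 <- sweep(positions, 2, c0)^2
  list(R_g = sqrt(sum(d2) / nrow(positions)),
       R_perp = sqrt(sum(d2[, 2:3]) / nrow(positions)),
       R_par = sqrt(sum(d2[, 1]) / nrow(positions)))
}

#' Chain span
#'
#' Axial span \eqn{S(x) = \max_i x_i - \min_i x_i} (the primary extension
#' measure along the channel axis) or the maximal pairwise Euclidean
#' distance \eqn{S(r)}.
#'
#' @param positions N x 3 matrix.
#' @param mode `"axial"` (default) or `"euclidean"`.
#' @return span in sigma.
#' @export
chain_span <- function(positions, mode = c("axial", "euclidean")) {
  mode <- match.arg(mode)
  if (mode == "axial") return(max(positions[, 1]) - min(positions[, 1]))
  max(stats::dist(positions))
}

#' Per-frame spans of a trajectory
#' @param traj a `trajectory`.
#' @param mode see [chain_span()].
#' @return numeric vector, one span per frame.
#' @export
span_series <- function(traj, mode = c("axial", "euclidean")) {
  mode <- match.arg(mode)
  if (mode == "axial") {
    x <- traj$frames[, , 1, drop = FALSE]
    return(apply(x, 1, max) - apply(x, 1, min))
  }
  vapply(seq_len(n_frames(traj)), function(i)
    chain_span(get_frame(traj, i), "euclidean"), 0)
}

#' Span histogram with 1-sigma bins
#'
#' Half-open bins `[a, b)` of width `binwidth` anchored at 0. `P(R)` is a
#' probability density: `sum(P) * binwidth == 1`.
#'
#' @param spans numeric vector of per-frame spans (pool repeats upstream).
#' @param binwidth bin width in sigma (default 1).
#' @return object of class `span_histogram`: data.frame with `R` (bin
#'   centre), `count`, `P`.
#' @export
span_histogram <- function(spans, binwidth = 1) {
  stopifnot(all(is.finite(spans)), length(spans) > 0)
  idx <- floor(spans / binwidth)
  rng <- range(idx)
  counts <- tabulate(idx - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  out <- data.frame(R = (rng[1]:rng[2] + 0.5) * binwidth, count = counts)
  out$P <- out$count / sum(out$count) / binwidth
  attr(out, "binwidth") <- binwidth
  attr(out, "n_frames") <- length(spans)
  class(out) <- c("span_histogram", "data.frame")
  out
}

#' Elastic free energy and restoring force from a span histogram
#'
#' \eqn{A(R) = c(T) - k_BT \ln P(R)} reported with \eqn{\min A = 0}, and
#' the restoring force \eqn{F = -dA/dR} by central finite differences on
#' the bin centres (one-sided at the ends). Empty bins are masked, not
#' interpolated.
#'
#' @param hist a [span_histogram()] (>= 2 non-empty bins).
#' @return data.frame with `R`, `A`, `force` (NA where masked).
#' @export
elastic_free_energy <- function(hist) {
  keep <- hist$count > 0
  if (sum(keep) < 2) stop("undefined: fewer than 2 non-empty bins")
  R <- hist$R[keep]
  A <- -log(hist$P[keep])
  A <- A - min(A)
  n <- length(A)
  force <- rep(NA_real_, n)
  if (n >= 2) {
    force[1] <- -(A[2] - A[1]) / (R[2] - R[1])
    force[n] <- -(A[n] - A[n - 1]) / (R[n] - R[n - 1])
    if (n >= 3)
      force[2:(n - 1)] <- -(A[3:n] - A[1:(n - 2)]) / (R[3:n] - R[1:(n - 2)])
  }
  data.frame(R = R, A = A, force = force)
}

#' Radial monomer distributions across the channel cross-section
#'
#' Monomers are counted in concentric shells of width `binwidth` in the
#' distance from the channel centre, measured both from the helical
#' mid-curve (with the same Newton nearest-point solver the dynamics use)
#' and from the major axis (the x-axis). Each profile is normalized to a
#' per-shell probability (shells sum to 1); shell volumes
#' \eqn{2\pi L_{ch} (0.5\sigma)^2 [(n+1)^2 - n^2]} are attached for
#' per-volume reweighting. For `R_H = 0` the two profiles coincide.
#'
#' @param traj a `trajectory`.
#' @param channel a [helix_channel()].
#' @param binwidth shell width in sigma (default 0.5).
#' @return list of two data.frames, `midcurve` and `axis`, each with
#'   `r` (shell centre), `r_rel` (r/R_ch), `count`, `P`, `shell_volume`.
#' @export
radial_profiles <- function(traj, channel, binwidth = 0.5) {
  if (n_frames(traj) == 0) stop("empty trajectory")
  pts <- matrix(aperm(traj$frames, c(2, 1, 3)), ncol = 3)
  d_mid <- nearest_helix_point(pts, channel)$distance
  d_axis <- sqrt(pts[, 2]^2 + pts[, 3]^2)
  prof <- function(d) {
    nb <- max(ceiling(channel$R_ch / binwidth), ceiling(max(d) / binwidth))
    idx <- pmin(floor(d / binwidth), nb - 1)
    counts <- tabulate(idx + 1L, nbins = nb)
    n <- 0:(nb - 1)
    data.frame(r = (n + 0.5) * binwidth, r_rel = (n + 0.5) * binwidth / channel$R_ch,
               count = counts, P = counts / sum(counts),
               shell_volume = 2 * pi * channel$L_ch * binwidth^2 * ((n + 1)^2 - n^2))
  }
  list(midcurve = prof(d_mid), axis = prof(d_axis))
}

#' Confinement free energy from the surface monomer density
#'
#' Integral of the monomer number density over the surface layer of
#' thickness `delta` (default \eqn{\sigma/5}) at the channel wall,
#' \eqn{A_C = 2\pi L_{ch}\int \phi_0(r)\,dr} over
#' \eqn{r \in (R_{ch}-\delta,\ R_{ch}]}: evaluated as the mean number of
#' wall-layer monomers per frame (in \eqn{\epsilon_0}, one unit per
#' contact). Zero for a chain on the axis; saturates at N when every bead
#' touches the wall; intensive in the number of frames.
#'
#' @param traj a `trajectory`.
#' @param channel a [helix_channel()].
#' @param delta surface layer thickness (sigma).
#' @return A_C in \eqn{\epsilon_0}.
#' @export
confinement_free_energy <- function(traj, channel, delta = 0.2) {
  if (n_frames(traj) == 0) stop("empty trajectory")
  pts <- matrix(aperm(traj$frames, c(2, 1, 3)), ncol = 3)
  d <- nearest_helix_point(pts, channel)$distance
  sum(d > channel$R_ch - delta) / n_frames(traj)
}

#' Bond orientational correlation function
#'
#' \eqn{\langle\cos\theta(s)\rangle}: mean dot product of unit bond
#' vectors at contour separation s, averaged over frames and bond pairs.
#' A free worm-like chain decays as \eqn{\exp(-s/P)}.
#'
#' @param traj a `trajectory` (or an N x 3 matrix for one conformation).
#' @param s_max maximum contour separation (sigma); default N/2.
#' @return data.frame with `s` and `cos_theta` (s = 0 gives exactly 1).
#' @export
orientational_correlation <- function(traj, s_max = NULL) {
  frames <- if (inherits(traj, "trajectory"))
    lapply(seq_len(n_frames(traj)), get_frame, traj = traj)
  else list(traj)
  nb <- nrow(frames[[1]]) - 1
  if (is.null(s_max)) s_max <- floor(nb / 2)
  s_max <- min(s_max, nb - 1)
  acc <- numeric(s_max + 1); cnt <- numeric(s_max + 1)
  for (f in frames) {
    b <- diff(f)
    b <- b / sqrt(rowSums(b^2))
    for (s in 0:s_max) {
      i <- seq_len(nb - s)
      acc[s + 1] <- acc[s + 1] + sum(rowSums(b[i, , drop = FALSE] * b[i + s, , drop = FALSE]))
      cnt[s + 1] <- cnt[s + 1] + length(i)
    }
  }
  data.frame(s = 0:s_max, cos_theta = acc / cnt)
}

#' Fit the persistence length from orientational correlations
#'
#' Least-squares fit of \eqn{\ln\langle\cos\theta\rangle = -s/P} over the
#' window `s <= s_fit` (positive correlations only).
#'
#' Points are weighted by \eqn{\langle\cos\theta\rangle^2} so the fit is
#' equivalent to least squares on the linear scale and the noisy tail of
#' the window does not dominate.
#'
#' @param oc data.frame from [orientational_correlation()].
#' @param s_fit fit window (sigma).
#' @return fitted P in sigma.
#' @export
fit_persistence_length <- function(oc, s_fit = 50) {
  sel <- oc$s <= s_fit & oc$cos_theta > 0 & oc$s > 0
  if (sum(sel) < 2) stop("not enough positive correlation points to fit")
  d <- oc[sel, ]
  fit <- lm(log(cos_theta) ~ 0 + s, data = d, weights = d$cos_theta^2)
  -1 / coef(fit)[[1]]
}

#' Odijk deflection length
#'
#' \eqn{\lambda = D^{2/3} P^{1/3}}: the typical contour distance between
#' wall deflections of a strongly confined semiflexible chain.
#'
#' @param D channel diameter (sigma).
#' @param P persistence length (sigma).
#' @return lambda in sigma.
#' @export
deflection_length <- function(D, P) {
  stopifnot(all(D > 0), all(P > 0))
  D^(2 / 3) * P^(1 / 3)
}

#' Scaling fits of span against confinement strength and force
#'
#' Three regime fits: the Odijk extension law
#' \eqn{R = L[1 - A (D/P)^{2/3}]} by least squares over
#' \eqn{D/P \in [0.5, 1]} (returns A); a log-log power-law exponent of
#' span against D/P over \eqn{D/P \in [1, 2]}; and a log-log force-law
#' exponent Y of span against compressive force (all supplied D/P pooled,
#' i.e. a concatenated fit).
#'
#' @param span_vs_DP data.frame with columns `DP` and `R` (may be NULL).
#' @param span_vs_F data.frame with columns `F` and `R` (optionally `DP`;
#'   may be NULL).
#' @param L contour length (sigma).
#' @return list with `A_odijk`, `exponent_DP`, `exponent_F` (NA where the
#'   corresponding table was not supplied).
#' @export
scaling_fits <- function(span_vs_DP = NULL, span_vs_F = NULL, L = 300) {
  A <- expDP <- expF <- NA_real_
  if (!is.null(span_vs_DP)) {
    d <- span_vs_DP[span_vs_DP$DP >= 0.5 - 1e-9 & span_vs_DP$DP <= 1 + 1e-9, ]
    if (nrow(d) >= 1) {
      # (1 - R/L) = A * (D/P)^(2/3): regression through the origin
      xx <- d$DP^(2 / 3); yy <- 1 - d$R / L
      A <- sum(xx * yy) / sum(xx^2)
    }
    d2 <- span_vs_DP[span_vs_DP$DP >= 1 - 1e-9, ]
    if (nrow(d2) >= 2) {
      if (any(d2$R <= 0)) stop("non-positive span in log-log fit")
      expDP <- coef(lm(log(R) ~ log(DP), data = d2))[[2]]
    }
  }
  if (!is.null(span_vs_F) && nrow(span_vs_F) >= 2) {
    if (any(span_vs_F$F <= 0) || any(span_vs_F$R <= 0))
      stop("non-positive values in log-log fit")
    expF <- coef(lm(log(R) ~ log(F), data = span_vs_F))[[2]]
  }
  list(A_odijk = A, exponent_DP = expDP, exponent_F = expF)
}

#' Predicted Odijk-regime span
#' @param L contour length (sigma).
#' @param DP confinement strength D/P.
#' @param A Odijk amplitude (default 0.1701, the cylindrical-channel value).
#' @return predicted span in sigma.
#' @export
odijk_span <- function(L, DP, A = 0.1701) L * (1 - A * DP^(2 / 3))

#' 2-D monomer density heat map
#'
#' Binned monomer density projected on the channel cross-section (`"yz"`)
#' or the side view (`"xy"`), normalized to a probability.
#'
#' @param traj a `trajectory`.
#' @param plane `"yz"` or `"xy"`.
#' @param binwidth bin width (sigma).
#' @return list with `x`, `y` bin centres and probability matrix `P`.
#' @export
projection_heatmap <- function(traj, plane = c("yz", "xy"), binwidth = 0.5) {
  plane <- match.arg(plane)
  pts <- matrix(aperm(traj$frames, c(2, 1, 3)), ncol = 3)
  cols <- if (plane == "yz") c(2, 3) else c(1, 2)
  u <- pts[, cols[1]]; v <- pts[, cols[2]]
  ub <- floor(u / binwidth); vb <- floor(v / binwidth)
  ur <- range(ub); vr <- range(vb)
  P <- matrix(0, ur[2] - ur[1] + 1, vr[2] - vr[1] + 1)
  for (i in seq_along(ub))
    P[ub[i] - ur[1] + 1, vb[i] - vr[1] + 1] <- P[ub[i] - ur[1] + 1, vb[i] - vr[1] + 1] + 1
  list(x = (ur[1]:ur[2] + 0.5) * binwidth,
       y = (vr[1]:vr[2] + 0.5) * binwidth,
       P = P / sum(P))
}

#' Running average of a series (equilibration monitor)
#' @param x numeric vector.
#' @return cumulative mean.
#' @export
running_average <- function(x) cumsum(x) / seq_along(x)
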