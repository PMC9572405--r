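#' Construct a closed polygonal curve
#'
#' @param vertices M x 3 matrix (>= 3 rows, no two consecutive vertices
#'   coincident; first and last vertex are joined by the closure segment).
#' @param provenance optional string describing how the curve was closed.
#' @return object of class `closed_curve` (an M x 3 matrix).
#' @export
closed_curve <- function(vertices, provenance = "as-given") {
  stopifnot(is.matrix(vertices), ncol(vertices) == 3, nrow(vertices) >= 3)
  d <- sqrt(rowSums((vertices - vertices[c(2:nrow(vertices), 1), ])^2))
  if (any(d < 1e-12)) {
    vertices <- vertices[d >= 1e-12, , drop = FALSE]  # drop exact duplicates
    if (nrow(vertices) < 3) stop("degenerate curve after removing duplicates")
  }
  structure(vertices, class = c("closed_curve", "matrix"),
            provenance = provenance)
}

random_directions <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Close an open chain into a polygon
#'
#' `"radial-outward"` (default, minimally interfering in spirit): each
#' endpoint is extended away from the chain centroid to a sphere of radius
#' 3x the maximal extent, and the two far points are joined by an arc on
#' that sphere, so the closure cannot thread the chain body.
#' `"direct-segment"` joins the endpoints directly; `"centroid-ray"`
#' routes both endpoints through a single far point on the sphere.
#'
#' @param chain N x 3 matrix of an open chain (N >= 3).
#' @param method closure scheme.
#' @return a [closed_curve()].
#' @export
close_curve <- function(chain,
                        method = c("radial-outward", "direct-segment", "centroid-ray")) {
  method <- match.arg(method)
  stopifnot(is.matrix(chain), ncol(chain) == 3)
  if (nrow(chain) < 3) stop("chain with < 3 beads cannot be closed")
  if (method == "direct-segment")
    return(closed_curve(chain, provenance = "direct-segment"))
  ctr <- colMeans(chain)
  rad <- 3 * max(sqrt(rowSums(sweep(chain, 2, ctr)^2)))
  far <- function(p) {
    v <- p - ctr
    l <- sqrt(sum(v^2))
    if (l < 1e-12) v <- c(1, 0, 0) else v <- v / l
    ctr + rad * v
  }
  a <- far(chain[1, ]); b <- far(chain[nrow(chain), ])
  if (method == "centroid-ray") {
    mid <- far(0.5 * (chain[1, ] + chain[nrow(chain), ]) +
                 c(0, 0, 1e-6))  # deterministic tie-break for antipodal ends
    verts <- rbind(chain, b, mid, a)
    return(closed_curve(verts, provenance = "centroid-ray"))
  }
  # great-circle arc from b to a on the sphere of radius rad about ctr
  va <- (a - ctr) / rad; vb <- (b - ctr) / rad
  cosang <- max(-1, min(1, sum(va * vb)))
  ang <- acos(cosang)
  arc <- if (ang < 1e-9) {
    matrix(numeric(0), 0, 3)
  } else {
    # slerp; if antipodal, pick a deterministic orthogonal waypoint
    axis <- if (abs(cosang + 1) < 1e-9) {
      w <- c(-vb[2], vb[1], 0)
      if (sum(w^2) < 1e-12) w <- c(0, -vb[3], vb[2])
      w / sqrt(sum(w^2))
    } else NULL
    nstep <- max(2, ceiling(ang / (pi / 16)))
    tt <- seq(0, 1, length.out = nstep + 1)[-c(1)]
    tt <- tt[-length(tt)]
    if (is.null(axis)) {
      t(vapply(tt, function(s) {
        v <- (sin((1 - s) * ang) * vb + sin(s * ang) * va) / sin(ang)
        ctr + rad * v
      }, numeric(3)))
    } else {
      t(vapply(tt, function(s) {
        v <- cos(s * ang) * vb + sin(s * ang) * axis
        ctr + rad * v
      }, numeric(3)))
    }
  }
  closed_curve(rbind(chain, b, arc, a), provenance = "radial-outward")
}

#' KMT simplification (3-D triangle elimination)
#'
#' Iteratively deletes vertex j whenever the triangle (j-1, j, j+1) is
#' pierced by no other segment of the curve (exact segment-triangle
#' intersection tests, conservative for degenerate geometry), until a
#' fixed point. Preserves the knot type.
#'
#' @param curve a [closed_curve()] (or an open N x 3 chain with
#'   `closed = FALSE`, whose endpoints are kept).
#' @param closed treat the polygon as closed.
#' @return the reduced curve (same class as the input).
#' @export
kmt_simplify <- function(curve, closed = inherits(curve, "closed_curve")) {
  out <- kmt_cpp(unclass(curve), closed)
  if (inherits(curve, "closed_curve"))
    closed_curve(out, provenance = attr(curve, "provenance"))
  else out
}

#' Alexander determinant |Delta(-1)|
#'
#' Builds a crossing diagram from a generic projection of the curve and
#' evaluates the Alexander determinant at t = -1 via the crossing-matrix
#' construction: 1 for the unknot, 3 for trefoils, 5 for the figure-eight.
#' Degenerate projections are retried with fresh random directions
#' (deterministic given the RNG state); the result is
#' projection-independent.
#'
#' @param curve a [closed_curve()].
#' @param simplify run [kmt_simplify()] first (recommended).
#' @param max_attempts projection retry budget.
#' @return integer determinant.
#' @export
alexander_determinant <- function(curve, simplify = TRUE, max_attempts = 100) {
  v <- if (simplify) unclass(kmt_simplify(curve)) else unclass(curve)
  for (jitter in 0:3) {
    if (jitter > 0) {
      # intrinsically singular curves (e.g. exactly overlapping segments)
      # are resolved by a topology-preserving micro-perturbation
      scale <- 1e-7 * max(apply(v, 2, function(x) diff(range(x))), 1)
      v <- v + matrix(rnorm(length(v), sd = scale), ncol = 3)
    }
    for (i in seq_len(max_attempts %/% 4)) {
      d <- alexander_det_cpp(v, random_directions(1)[1, ])
      if (d >= 0) return(as.integer(d))
    }
  }
  stop("no regular projection found after ", max_attempts, " attempts")
}

#' Gauss-integral writhe of a polygonal curve
#'
#' Discretized Gauss double integral: exact analytic solid-angle
#' contribution summed over all non-adjacent segment pairs. Right-handed
#' crossings count positive. Equals the average signed crossing number
#' over uniformly random projections.
#'
#' @param curve a [closed_curve()] or an open N x 3 chain.
#' @param closed treat as closed.
#' @return writhe (numeric).
#' @export
writhe_gauss <- function(curve, closed = inherits(curve, "closed_curve")) {
  writhe_gauss_cpp(unclass(curve), closed)
}

#' Average crossing number over random projections
#'
#' Mean unsigned crossing count over `n_projections` directions drawn
#' uniformly on the sphere (reproducible given the RNG seed). Works on the
#' open 3-D curve; no closure is applied.
#'
#' @param curve N x 3 chain or [closed_curve()].
#' @param n_projections number of random projections (default 2000).
#' @param closed treat as closed.
#' @return ACN (numeric).
#' @export
acn <- function(curve, n_projections = 2000,
                closed = inherits(curve, "closed_curve")) {
  stopifnot(n_projections >= 1)
  dirs <- random_directions(n_projections)
  cr <- crossings_project_cpp(unclass(curve), closed, dirs)
  ok <- cr[, 3] == 0
  mean(cr[ok, 1] + cr[ok, 2])
}

#' Signed crossing counts of the minimal-crossing projection
#'
#' Projects the (ideally KMT-simplified) curve along sampled random
#' directions, picks the projection with the fewest crossings, and counts
#' positive/negative crossings by the right-hand rule. The core writhe is
#' `n_plus - n_minus`.
#'
#' @param curve a [closed_curve()] (apply [kmt_simplify()] first for the
#'   knotted-core diagram) or open chain.
#' @param n_projections directions sampled (degenerate ones are skipped).
#' @param closed treat as closed.
#' @return list with `n_plus`, `n_minus`, `core_writhe`, `n_crossings`.
#' @export
signed_crossing_counts <- function(curve, n_projections = 50,
                                   closed = inherits(curve, "closed_curve")) {
  dirs <- random_directions(n_projections)
  cr <- crossings_project_cpp(unclass(curve), closed, dirs)
  ok <- which(cr[, 3] == 0)
  if (!length(ok)) stop("all projections degenerate")
  tot <- cr[ok, 1] + cr[ok, 2]
  best <- ok[which.min(tot)]
  list(n_plus = as.integer(cr[best, 1]), n_minus = as.integer(cr[best, 2]),
       core_writhe = as.integer(cr[best, 1] - cr[best, 2]),
       n_crossings = as.integer(cr[best, 1] + cr[best, 2]))
}

.det_table <- list(
  # minimal crossing number k -> named determinants of the Rolfsen knots
  "3" = c("3_1" = 3),
  "4" = c("4_1" = 5),
  "5" = c("5_1" = 5, "5_2" = 7),
  "6" = c("6_1" = 9, "6_2" = 11, "6_3" = 13),
  "7" = c("7_1" = 7, "7_2" = 11, "7_3" = 13, "7_4" = 15, "7_5" = 17,
          "7_6" = 19, "7_7" = 21))
.achiral <- c("4_1", "6_3")

#' Knot class label from determinant and diagram crossing count
#'
#' Lookup by (Alexander determinant, minimal observed crossing count):
#' determinant 1 is the unknot 0_1; chiral classes carry an `m` suffix
#' when the core writhe is negative (e.g. `3_1` vs `3_1m`). Diagrams with
#' more than 11 crossings are labelled `"complex, k > 11"`; combinations
#' not in the table give `"unresolved(k)"`.
#'
#' @param determinant Alexander determinant |Delta(-1)|.
#' @param n_crossings minimal crossing count observed over projections.
#' @param core_writhe signed crossing excess of the minimal diagram
#'   (chirality sign).
#' @return character label.
#' @export
knot_class <- function(determinant, n_crossings, core_writhe = 0) {
  if (is.na(determinant)) determinant <- Inf
  if (determinant == 1) return("0_1")
  if (n_crossings > 11) return("complex, k > 11")
  if (n_crossings < 3) return(sprintf("unresolved(%d)", as.integer(n_crossings)))
  # prefer the class whose minimal diagram matches the observed crossing
  # count, then fall back to fewer-crossing classes (the observed diagram
  # may not be minimal)
  for (k in seq(min(n_crossings, 7), 3)) {
    tab <- .det_table[[as.character(k)]]
    hit <- names(tab)[tab == determinant]
    if (length(hit)) {
      lab <- hit[1]
      if (!(lab %in% .achiral) && core_writhe < 0) lab <- paste0(lab, "m")
      return(lab)
    }
  }
  sprintf("unresolved(%d)", as.integer(n_crossings))
}

#' Locate the knotted core of an open chain
#'
#' Shortest contiguous subchain that remains knotted under closure, found
#' by bidirectional shrinking: each end advances while the closed subchain
#' keeps the full chain's determinant.
#'
#' @param chain N x 3 open chain.
#' @param method closure scheme (see [close_curve()]).
#' @return list with `start`, `end` bead indices (both `NA` and
#'   `knotted = FALSE` for an unknotted chain).
#' @export
locate_knot_core <- function(chain, method = "radial-outward") {
  det_of <- function(sub) alexander_determinant(close_curve(sub, method))
  full <- det_of(chain)
  if (full == 1) return(list(start = NA_integer_, end = NA_integer_, knotted = FALSE))
  s <- 1L; e <- nrow(chain)
  repeat {
    moved <- FALSE
    if (e - s >= 3 && det_of(chain[(s + 1):e, , drop = FALSE]) == full) {
      s <- s + 1L; moved <- TRUE
    }
    if (e - s >= 3 && det_of(chain[s:(e - 1), , drop = FALSE]) == full) {
      e <- e - 1L; moved <- TRUE
    }
    if (!moved) break
  }
  list(start = s, end = e, knotted = TRUE)
}

#' Full knot report for one conformation
#'
#' Closure, KMT simplification, Alexander determinant, class label with
#' chirality, signed crossing counts of the simplified diagram, Gauss
#' writhe of the chain, and optionally ACN and the knotted-core interval.
#'
#' @param chain N x 3 open chain (a trajectory frame).
#' @param closure closure scheme.
#' @param n_projections directions for the minimal-crossing diagram.
#' @param acn_projections projections for the ACN (0 skips it).
#' @param locate_core also run [locate_knot_core()] (slow).
#' @return list of class `knot_report`.
#' @export
knot_report <- function(chain, closure = "radial-outward",
                        n_projections = 50, acn_projections = 0,
                        locate_core = FALSE) {
  cc <- close_curve(chain, closure)
  simp <- kmt_simplify(cc)
  det <- alexander_determinant(simp, simplify = FALSE)
  sc <- signed_crossing_counts(simp, n_projections)
  cls <- knot_class(det, sc$n_crossings, sc$core_writhe)
  core <- if (locate_core) locate_knot_core(chain, closure)
          else list(start = NA_integer_, end = NA_integer_, knotted = det != 1)
  structure(list(determinant = det, knot_class = cls,
                 n_plus = sc$n_plus, n_minus = sc$n_minus,
                 core_writhe = sc$core_writhe, n_crossings = sc$n_crossings,
                 chain_writhe = writhe_gauss(chain, closed = FALSE),
                 acn = if (acn_projections > 0) acn(chain, acn_projections, closed = FALSE) else NA_real_,
                 core_start = core$start, core_end = core$end,
                 knotted = det != 1),
            class = "knot_report")
}

#' @export
print.knot_report <- function(x, ...) {
  cat(sprintf("<knot_report> %s (det %s), diagram %d crossings (%d+/%d-), core writhe %d, chain writhe %.3f\n",
              x$knot_class, format(x$determinant), x$n_crossings,
              x$n_plus, x$n_minus, x$core_writhe, x$chain_writhe))
  invisible(x)
}

#' Knot spectrum of a trajectory
#'
#' Per-frame knot reports summarized as class frequencies (probabilities
#' sum to 1) plus the mean chain writhe and knotting probability
#' `1 - P(0_1)`.
#'
#' @param traj a `trajectory`, or a list of N x 3 frames.
#' @param frames frame indices to analyse (default: all).
#' @param ... passed to [knot_report()].
#' @return list with `classes` (named probability vector), `p_knotted`,
#'   `mean_writhe`, and the per-frame `reports`.
#' @export
knot_spectrum <- function(traj, frames = NULL, ...) {
  flist <- if (inherits(traj, "trajectory")) {
    if (is.null(frames)) frames <- seq_len(n_frames(traj))
    lapply(frames, get_frame, traj = traj)
  } else traj
  reports <- lapply(flist, knot_report, ...)
  cls <- vapply(reports, `[[`, "", "knot_class")
  tab <- table(cls) / length(cls)
  list(classes = setNames(as.numeric(tab), names(tab)),
       p_knotted = mean(vapply(reports, `[[`, TRUE, "knotted")),
       mean_writhe = mean(vapply(reports, `[[`, 0, "chain_writhe")),
       reports = reports)
}
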