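---
title: "Models and methods behind helixknot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind helixknot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

helixknot simulates double-stranded DNA as a discretized semi-flexible
worm-like chain of $N$ beads (default 300). One bead stands for 8.5 bp of
hydrated DNA, with a diameter of $\sigma = 2.5$ nm; the default chain is
therefore 2.55 kbp, the size of a small plasmid. All quantities are in
reduced units: length in $\sigma$, energy in $\epsilon_0 = k_BT$, time in
$\tau$ (74 ns), bead mass $m = 1$.

Three bonded/non-bonded interactions define the force field:

* **Bond stretching** $U_s(r) = k_s (r - r_0)^2$ with $k_s =
  80\,\epsilon_0/\sigma^2$ and $r_0 = 1\,\sigma$. The stiff bond prevents
  artificial strand passage under strong compression.
* **Bending** about the straight angle $\theta_0 = \pi$, harmonic in the
  angle. The package evaluates $U_b = (k_b/2)(\theta-\theta_0)^2$ with
  $k_b = 20$ by default (`bend_convention = "half"`, the convention of
  common simulation engines), which reproduces a persistence length of
  $P \approx 20\,\sigma = 50$ nm — the experimental value for dsDNA. A
  bare-prefactor variant (`"bare"`, $U_b = k_b(\theta-\theta_0)^2$) is
  exposed because the two conventions coexist in the literature; the bare
  form with $k_b = 20$ would instead give $P \approx 40\,\sigma$. The
  half-prefactor choice is pinned by the persistence-length recovery test,
  not by taste: simulated free chains must fit
  $\langle\cos\theta(s)\rangle = e^{-s/P}$ with $P = 20\,\sigma \pm 10\%$.
* **Excluded volume**: the fully repulsive WCA potential
  $U_{ex}(r) = 4\epsilon_0[(\sigma/r)^{12} - (\sigma/r)^{6} + 1/4]$ cut at
  $2^{1/6}\sigma$, applied to all bead pairs except directly bonded
  neighbours (excluding the bonded pair avoids double-penalizing the
  bond; the chain is nicked/torsionally relaxed, so no twist term is
  used).

The chain obeys the Langevin equation
$m\ddot r = -\gamma m \dot r - \nabla U + R(t)\,(2\epsilon_0 m\gamma)^{1/2}$
with $\delta$-correlated Gaussian noise $R(t)$, integrated with the BAOAB
splitting at $d\tau = 0.01\,\tau$. BAOAB was chosen over naive
Langevin-Euler schemes for its accurate configurational sampling at this
time step; with $\gamma = 0$ it reduces exactly to velocity Verlet, which
the test suite uses as an NVE control. The friction $\gamma = 1\,\tau^{-1}$
and $m = 1$ are package defaults (they set kinetics, not equilibrium
averages) and are configurable.

# Implicit helical confinement

The confining channel is a tube of radius $R_{ch}$ ($D = 2R_{ch}$) around
the helical mid-curve
$$r_0(t) = \big(k\,t,\; R_H\cos\omega t,\; R_H\sin\omega t\big),$$
with helix radius $R_H$ (default $R_{ch}/3$), pitch parameter
$k = D/2\pi$ — so the loop spacing $d_H = 2\pi k$ equals $D$ and the
channel family is self-similar across diameters — and handedness
$\omega = \pm 1$. $R_H = 0$ recovers the cylinder exactly.

The wall is *implicit*: each step, every bead's nearest mid-curve point is
found by Newton iteration on the stationarity condition
$$g(t) = k(x - kt) - R_H\,\omega\,(y\sin\omega t - z\cos\omega t) = 0,$$
started from the axial projection $t_0 = x/k$ (warm-started from the
previous step inside the integrator). Inside the tube the root is unique
whenever $2\pi k > R_{ch}$, which all supported geometries satisfy.
Numerical policy: $|g| < 10^{-10}$ within 50 iterations, a trust region of
one pitch per Newton step, and a bisection fallback bracketed one pitch
around $t_0$; the solver is validated against a dense grid search to
$|\Delta d| < 10^{-8}\sigma$ on randomized channels. The wall force is a
WCA repulsion on the surface gap $g_w = R_{ch} - d$ with length scale
$\sigma/2$ (the bead radius), so the wall is soft on the scale of the
bead, as in engine-style implicit constraints. An identical WCA-on-gap
form acts at the bottom wall plane $x = 0$ when compression is simulated.

# Piston compression

Compression uses a piston bead of radius $100\,\sigma$ whose centre is
constrained to the channel axis. It ignores the walls, repels the polymer
through a WCA interaction on $r - 99.5\,\sigma$ (contact at the piston
surface), and moves by overdamped 1-D Langevin dynamics under the applied
force $-F$ plus the polymer's reaction, with friction $200\gamma$ (the
piston/bead radius ratio) and thermal noise (a quasi-static,
non-thermostatted piston is available as an option). Supported forces
cover $F\sigma/\epsilon_0 \in \{0, 0.1, 0.35, 0.5, 1, 2, 5, 10, 15, 20\}$,
from weak to strong compression.

Initial conformations are straight chains along the channel *axis* at
1-σ spacing. The axis lies inside the helical tube for every supported
geometry ($R_H = R_{ch}/3$), so the start is wall-violation-free, and it
is close to the extended "I" conformations that dominate at strong
confinement. Laying the chain along the helical mid-curve instead (kept
as an option) starts it wound through the grooves; desk-scale runs then
spend most of their budget unwinding toward the straighter equilibrium,
so the axis start is the default. For *free* chains the
`init = "wlc"` protocol draws the initial bending angles from the
equilibrium discrete worm-like-chain distribution, which removes the very
slow decorrelation of long-wavelength tangent modes entirely.

# Observables

* **Span**: axial $S(x) = \max_i x_i - \min_i x_i$ (the default extension
  measure; the all-coordinate $S(r)$ is biased for strongly compressed
  chains lying flat at the channel bottom and is kept secondary),
  histogrammed in half-open 1-σ bins anchored at 0.
* **Elastic free energy** $A(R) = c(T) - k_BT\ln P(R)$ reported with
  $\min A = 0$; the restoring force $F = -dA/dR$ by central differences,
  one-sided at the window ends, empty bins masked and never interpolated
  (smoothing is a presentation choice, not part of the estimator).
* **Radial distributions** in 0.5-σ shells of distance from the channel
  centre, measured both from the helical mid-curve — using the same
  Newton solver as the dynamics — and from the major axis; normalized to
  per-shell probabilities (the per-volume density is recoverable from the
  attached shell volumes $2\pi L_{ch}(0.5\sigma)^2[(n+1)^2 - n^2]$).
* **Confinement free energy** $A_C$: the integral of the monomer number
  density over the surface layer $\delta = \sigma/5$ at the wall,
  evaluated as the mean number of wall-layer monomers per frame (one
  $\epsilon_0$ per contact).
* **Orientational correlations** $\langle\cos\theta(s)\rangle$ over bond
  pairs and frames; persistence fits use weighted least squares on the
  log-scale (weights $\langle\cos\theta\rangle^2$, equivalent to linear-
  scale least squares) over $s \le 50\,\sigma$, so the noisy tail of the
  window cannot dominate the slope.
* **Scaling fits**: the Odijk extension law $R = L[1 - A(D/P)^{2/3}]$
  fitted through the origin on $D/P \in [0.5, 1]$; log–log power laws for
  $D/P \in [1, 2]$ and for span versus force (the force fit pools all
  supplied confinement strengths, i.e. a concatenated fit). The Odijk
  deflection length is $\lambda = D^{2/3}P^{1/3}$.

# Knot analysis

Knots exist on closed curves, so open frames are closed first. The default
**radial-outward closure** sends each endpoint away from the chain
centroid to a sphere of radius three times the maximal extent and joins
the two far points by a great-circle arc on that sphere — in the spirit of
minimally interfering closure, the closure arc stays far from the chain
body so it cannot thread it. Direct-segment and centroid-ray closures are
available for cross-checks; fixtures verify that all of them preserve the
knot type of benign inputs.

The closed polygon is reduced by **KMT triangle elimination**: vertex $j$
is deleted whenever no other segment pierces the triangle
$(j-1, j, j+1)$, iterated to a fixed point. The intersection test is
conservative — degenerate or near-coplanar geometry blocks deletion — so
simplification can stall early but never changes the knot type.

Knot typing evaluates the **Alexander determinant** $|\Delta(-1)|$ from a
generic projection of the simplified curve via the standard crossing-
matrix construction (at $t = -1$ the matrix is independent of crossing
signs). Degenerate projections — tangencies, endpoint hits, coincident
crossings — are detected and retried with fresh random directions. The
determinant distinguishes the unknot (1), trefoil (3) and figure-eight
(5); classes are labelled by a (determinant, minimal observed crossing
count) table through 7-crossing knots, `"complex, k > 11"` beyond 11
diagram crossings, and `"unresolved(k)"` otherwise — matching the
information an Alexander-based pipeline actually has. Chirality cannot
come from the determinant, so handedness labels (3~1~ vs 3~1~m) come from
the sign of the **core writhe** $n_+ - n_-$, the signed crossing excess of
the minimal-crossing projection found over sampled directions.

Geometric entanglement uses the open 3-D curve directly: **writhe** by
the exact pairwise solid-angle form of the discretized Gauss double
integral (right-handed crossings positive), and the **average crossing
number** as the mean unsigned crossing count over random projections
(2000 by default, no closure). The two routes check each other: writhe
must equal the projection-averaged *signed* crossing count, and the test
suite enforces agreement within 0.02 at 5000 projections. The
**knotted core** is localized by bidirectional shrinking of the open
chain while the closed subchain keeps the full chain's determinant.

# Synthetic data

`make_curve()` provides deterministic parametric fixtures — circle, torus
knots $(p,q)$ (with $n \ge 3pq$ vertices so the discretization is
faithful), figure-eight, straight rod — and a discrete worm-like-chain
random walk whose bend angles are Rayleigh$(1/\sqrt{P})$ draws, the
equilibrium distribution of the harmonic bending energy under the
small-angle solid-angle measure; its tangent correlations decay as
$e^{-s/P}$ by construction. `handedness = -1` is the exact z-mirror.
These fixtures exercise every topology and observable path without
simulation; what they do *not* emulate is excluded volume (the walk may
self-intersect) or confinement, so passing fixture tests validates the
estimators, while statements about confined DNA rest on the MD runs.
Fixture RNG streams are seeded locally and never perturb simulation
reproducibility.

# Mirror equivariance and the chirality claim

The mid-curve's handedness lives entirely in the sign of the z-phase, so
the z = 0 plane mirrors a $+\omega$ channel onto the $-\omega$ channel.
Every arithmetic path in the engine commutes with that reflection;
negating the z-components of the initial velocities and of the thermal
noise stream (`mirror_noise = TRUE`) therefore yields *bitwise*-mirrored
trajectories. This is the mechanistic basis of the handedness claim: any
statistical writhe bias between $+\omega$ and $-\omega$ channels can only
come from the channel geometry, never from the integrator. The
headline property is tested statistically in scaled-down compressed runs
(D/P = 1, $F\sigma/\epsilon_0 = 1$, N = 150, five seeds per handedness):
a one-sided sign test that each run's mean chain writhe carries the sign
its channel's handedness predicts, plus a check that helical channels
knot at least as readily as cylindrical ones. At desk scale the
handedness imprint on the writhe is real but weak relative to per-run
conformational noise (see the limitations below), so the sign test is
the suite's most demanding assertion.

# Problem sizes and numerical choices

Desk-scale defaults replace the production protocol of $10^9$ steps with
runs sized by convergence monitoring (running averages of the span):
confined-span runs use $4$–$5\times10^5$ pre-equilibration plus
$6$–$8\times10^5$ production steps per seed with three to five seeds;
persistence-length estimation pools tangent correlations over ~20 short
runs ($1.5\times10^5$ steps each), because every `init = "wlc"` start is
an independent equilibrium draw of the slow tangent modes — many short
runs sample them far more efficiently than one long trajectory, whose
single-seed fits scatter by $\pm 25\%$;
compression runs use $1.2\times10^6$ pre-equilibration steps plus up to
$8\times10^5$ production steps, long enough for the piston (drift speed
$F/200\gamma$) to reach mechanical equilibrium at $F \ge 1$. At these
scales the cylinder/helix span means at D/P = 0.5 reproduce the
strong-confinement reference values within 2%.

Remaining known limitations, stated plainly:

* The span difference between helical and cylindrical channels at
  D/P = 0.5 is a ~1.5% effect probed with ~1% statistics at desk scale;
  the *equality* checks against the reference spans pass robustly, but
  the helical-minus-cylindrical *sign* at five seeds is within seed
  noise, so the directional comparison is the least robust assertion in
  the suite and can fail at desk scale while holding at production
  scale.
* The span-versus-force log-log slope at D/P = 1 over
  $F\sigma/\epsilon_0 \in [2, 20]$ does not reach the theoretical
  $-9/4$: the axial span saturates at the size of the spooled state for
  $F \ge 10$ (a bounded chain cannot keep decaying as $F^{-9/4}$ over a
  decade), so the whole-window fit levels off near $-1.5$ to $-1.7$; the
  *local* slope steepens through $-9/4$ between $F = 5$ and $10$.
* Knotting at $F = 1$, D/P = 1 is driven by compression waiting time;
  at desk scale knotted frames are rare in every channel geometry, so
  the helical-versus-cylindrical knotting comparison is made as a
  one-sided test against a helical *deficit* rather than a comparison
  of two near-zero point estimates.
* Alexander determinants above 11 diagram crossings are reported but
  not used for classification.
* The soft WCA wall means the *effective* channel diameter is a
  fraction of a bead radius smaller than the nominal $D$ — the standard
  soft-wall convention of engine-style implicit constraints.
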