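test_that("Alexander determinants of the canonical fixtures", {
  set.seed(41)
  expect_identical(alexander_determinant(make_curve("circle", n = 60)), 1L)
  expect_identical(alexander_determinant(trefoil()), 3L)
  expect_identical(alexander_determinant(fig8()), 5L)
})

test_that("determinant is independent of the projection direction", {
  set.seed(42)
  for (curve in list(trefoil(100), fig8(160), make_curve("circle", n = 40))) {
    simp <- kmt_simplify(curve)
    dets <- replicate(12, {
      d <- -1
      while (d < 0) d <- helixknot:::alexander_det_cpp(unclass(simp), rand_dirs(1)[1, ])
      d
    })
    expect_equal(length(unique(dets)), 1L)
  }
})

test_that("KMT simplification preserves knot type and reaches fixed points", {
  set.seed(43)
  # planar convex polygon reduces to a triangle
  hex <- closed_curve(cbind(cos(seq(0, 2 * pi, length.out = 7)[-7]),
                            sin(seq(0, 2 * pi, length.out = 7)[-7]), 0))
  expect_equal(nrow(kmt_simplify(hex)), 3L)
  # 300-vertex trefoil keeps determinant 3 and shrinks a lot
  t300 <- trefoil(300)
  s <- kmt_simplify(t300)
  expect_lt(nrow(s), 30)
  expect_identical(alexander_determinant(s, simplify = FALSE), 3L)
  # idempotent after convergence
  expect_equal(unclass(kmt_simplify(s)), unclass(s))
})

test_that("closure preserves the topology of benign cuts and detects knots", {
  set.seed(44)
  # closed circle cut at a vertex and re-closed: still the unknot
  circ <- make_curve("circle", n = 80)
  expect_identical(alexander_determinant(close_curve(unclass(circ))), 1L)
  # open straight rod: unknot under all methods
  rod <- make_curve("rod", n = 50)
  for (m in c("radial-outward", "direct-segment", "centroid-ray"))
    expect_identical(alexander_determinant(close_curve(rod, m)), 1L)
  # open trefoil (5% trimmed): determinant 3 under radial-outward closure
  t <- unclass(trefoil(200))
  open_t <- t[6:195, ]
  expect_identical(alexander_determinant(close_curve(open_t)), 3L)
  expect_error(close_curve(t[1:2, ]), "3 beads")
})

test_that("Gauss writhe: planar curves, parity, and the projection oracle", {
  expect_equal(writhe_gauss(make_curve("circle", n = 60)), 0, tolerance = 1e-10)
  # mirror flips the sign exactly
  for (n in c(100, 140)) {
    wr_p <- writhe_gauss(trefoil(n, handedness = +1))
    wr_m <- writhe_gauss(trefoil(n, handedness = -1))
    expect_identical(wr_p, -wr_m)
    expect_gt(wr_p, 0)  # right-handed trefoil: positive writhe
  }
  # writhe equals the mean signed crossing number over 5000 projections
  set.seed(45)
  curves <- c(lapply(1:3, function(s) random_open_chain(25, seed = s)),
              list(unclass(trefoil(80)), unclass(fig8(100))))
  closed_flags <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  for (i in seq_along(curves)) {
    wr <- writhe_gauss(curves[[i]], closed = closed_flags[i])
    cr <- helixknot:::crossings_project_cpp(curves[[i]], closed_flags[i],
                                            rand_dirs(5000))
    ok <- cr[, 3] == 0
    expect_lt(abs(wr - mean(cr[ok, 1] - cr[ok, 2])), 0.02)
  }
})

test_that("ACN: bounds, seed reproducibility and mirror invariance", {
  tre <- trefoil(100)
  set.seed(46); a1 <- acn(tre, 400)
  set.seed(46); a2 <- acn(tre, 400)
  expect_identical(a1, a2)
  expect_gte(a1, 3)          # crossing-number lower bound for a trefoil
  expect_gte(a1, abs(writhe_gauss(tre)) - 0.3)
  # mirror pair under mirrored directions: crossing counts swap sign exactly
  set.seed(47)
  dirs <- rand_dirs(64)
  cr_p <- helixknot:::crossings_project_cpp(unclass(tre), TRUE, dirs)
  cr_m <- helixknot:::crossings_project_cpp(unclass(trefoil(100, handedness = -1)),
                                            TRUE, dirs %*% diag(c(1, 1, -1)))
  expect_identical(cr_p[, 1], cr_m[, 2])
  expect_identical(cr_p[, 2], cr_m[, 1])
})

test_that("signed crossings of minimal diagrams and chirality labels", {
  set.seed(48)
  sc <- signed_crossing_counts(kmt_simplify(trefoil(150)))
  expect_identical(c(sc$n_plus, sc$n_minus), c(3L, 0L))
  sc_m <- signed_crossing_counts(kmt_simplify(trefoil(150, handedness = -1)))
  expect_identical(c(sc_m$n_plus, sc_m$n_minus), c(0L, 3L))
  # unknot: (0, 0) after simplification
  sc_u <- signed_crossing_counts(kmt_simplify(make_curve("circle", n = 50)))
  expect_identical(c(sc_u$n_plus, sc_u$n_minus), c(0L, 0L))
})

test_that("knot class lookup covers the small-knot table and edge labels", {
  expect_equal(knot_class(1, 0), "0_1")
  expect_equal(knot_class(3, 3, core_writhe = 3), "3_1")
  expect_equal(knot_class(3, 3, core_writhe = -3), "3_1m")
  expect_equal(knot_class(5, 4), "4_1")   # achiral: no m suffix
  expect_equal(knot_class(5, 4, core_writhe = -2), "4_1")
  expect_equal(knot_class(5, 5, core_writhe = 5), "5_1")
  expect_equal(knot_class(7, 5), "5_2")
  expect_equal(knot_class(99, 13), "complex, k > 11")
  expect_match(knot_class(23, 8), "unresolved")
})

test_that("a (2,13) torus knot is classified as complex", {
  set.seed(49)
  k213 <- make_curve("torus_knot", n = 200, p = 2, q = 13)
  rep <- knot_report(unclass(k213)[1:199, ])  # cut one vertex, reclose
  expect_equal(rep$knot_class, "complex, k > 11")
})

test_that("knot core localizes a trefoil spliced into a straight chain", {
  set.seed(50)
  t <- unclass(trefoil(90)) * 2           # open trefoil arc
  t_open <- t[4:87, ]
  # straight leads leave each end radially outward from the knot body, so
  # they cannot thread the knot and the core is the spliced arc
  ctr <- colMeans(t_open)
  out_dir <- function(p) (p - ctr) / sqrt(sum((p - ctr)^2))
  d1 <- out_dir(t_open[1, ]); d2 <- out_dir(t_open[nrow(t_open), ])
  lead <- matrix(t_open[1, ], 40, 3, byrow = TRUE) + outer(seq(40, 1), d1)
  tailm <- matrix(t_open[nrow(t_open), ], 40, 3, byrow = TRUE) + outer(seq(1, 40), d2)
  chain <- rbind(lead, t_open, tailm)
  core <- locate_knot_core(chain)
  expect_true(core$knotted)
  expect_gt(core$start, 20)                # excludes most of the straight lead
  expect_lt(core$end, nrow(chain) - 20)
  # unknotted rod: empty core, signalled not errored
  expect_false(locate_knot_core(make_curve("rod", n = 30))$knotted)
})

test_that("knot spectrum counts classes and normalizes", {
  set.seed(51)
  frames <- list(make_curve("rod", n = 40), make_curve("rod", n = 40) +
                   matrix(rnorm(120, sd = 0.01), ncol = 3),
                 unclass(trefoil(120))[3:118, ])
  sp <- knot_spectrum(frames)
  expect_equal(sum(sp$classes), 1, tolerance = 1e-12)
  expect_equal(sp$classes[["0_1"]], 2 / 3)
  expect_equal(sp$p_knotted, 1 / 3)
})

test_that("full parity suite: every topological output transforms correctly under mirroring", {
  set.seed(52)
  for (hand in list(c(+1, -1))) {
    a <- trefoil(130, handedness = +1)
    b <- trefoil(130, handedness = -1)
    expect_identical(alexander_determinant(a), alexander_determinant(b))
    expect_identical(writhe_gauss(a), -writhe_gauss(b))
    sa <- signed_crossing_counts(kmt_simplify(a))
    sb <- signed_crossing_counts(kmt_simplify(b))
    expect_identical(sa$core_writhe, -sb$core_writhe)
    expect_equal(knot_class(3, 3, sa$core_writhe), "3_1")
    expect_equal(knot_class(3, 3, sb$core_writhe), "3_1m")
  }
})
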