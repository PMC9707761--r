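# Geometric feature definitions, documented ranges, special values, and
# rigid-motion invariance.

test_that("distances and ratios follow their definitions", {
  expect_equal(lateral_pair_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(lateral_pair_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(31)
  a <- rnorm(3); b <- rnorm(3)
  expect_equal(lateral_pair_distance(a, b), sqrt(sum((a - b)^2)))
  expect_equal(lateral_pair_distance(a, b), lateral_pair_distance(b, a))

  expect_equal(side_chord_length(c(0, 0, 0), c(0, 0, 2)), 2)
  # triangle inequality on random triples
  for (i in 1:20) {
    p <- matrix(rnorm(9), 3L)
    expect_lte(side_chord_length(p[1, ], p[3, ]),
               side_chord_length(p[1, ], p[2, ]) +
                 side_chord_length(p[2, ], p[3, ]) + 1e-12)
  }

  pi_ <- make_pair(c(0, 0, 0), c(1, 0, 0), half_width = 1)
  pj <- make_pair(c(0, 5, 0), c(1, 0, 0), half_width = 0.5)
  expect_equal(pair_distance_ratio(pi_, pj), 2)
  expect_equal(pair_distance_ratio(pj, pi_), 0.5)
  expect_equal(pair_distance_ratio(pi_, pi_), 1)
  expect_error(pair_distance_ratio(pi_, rbind(c(0, 0, 0), c(0, 0, 0))),
               "degenerate")

  expect_equal(midpoint_distance(pi_, pj), 5)
  expect_equal(midpoint_distance(pi_, make_pair(c(0, 0, 0), c(0, 1, 0))), 0)
})

test_that("cosine similarities compare side chords as documented", {
  pi_ <- make_pair(c(0, 0, 0), c(1, 0, 0))
  pj <- make_pair(c(0, 5, 0), c(1, 0, 0))
  pk <- make_pair(c(0, 10, 0), c(1, 0, 0))
  # parallel sides: same-segment left-vs-right cosine is 1
  expect_equal(side_cosine_similarity(pi_, pj), 1)
  # successive-chord comparison returns one cosine per side
  expect_equal(unname(side_cosine_similarity(pi_, pj, pk)), c(1, 1))
  # antiparallel and orthogonal configurations
  expect_equal(side_cosine_similarity(rbind(c(-1, 0, 0), c(1, 0, 0)),
                                      rbind(c(-1, 5, 0), c(1, -5, 0))), -1)
  orth <- side_cosine_similarity(rbind(c(-1, 0, 0), c(1, 0, 0)),
                                 rbind(c(-1, 5, 0), c(1, 0, 5)))
  expect_equal(orth, 0)
})

test_that("twist angles carry the documented sign and range conventions", {
  pi_ <- make_pair(c(0, 0, 0), c(1, 0, 0))
  # untwisted coplanar pairs
  pj0 <- make_pair(c(0, 5, 0), c(1, 0, 0))
  expect_equal(axial_twist_angle(pi_, pj0), 0)
  expect_equal(lateral_axial_twist_angle(pi_, pj0), 0)
  # quarter twist about the midpoint chord
  pj90 <- make_pair(c(0, 5, 0), c(0, 0, 1))
  expect_equal(abs(axial_twist_angle(pi_, pj90)), 90)
  expect_equal(lateral_axial_twist_angle(pi_, pj90), 90)
  # opposed axes
  pj180 <- make_pair(c(0, 5, 0), c(-1, 0, 0))
  expect_equal(lateral_axial_twist_angle(pi_, pj180), 180)
  # the signed angle flips under mirror reflection of all nuclei
  set.seed(32)
  for (i in 1:10) {
    a <- make_pair(rnorm(3), .unit3(rnorm(3)))
    b <- make_pair(rnorm(3) + c(5, 0, 0), .unit3(rnorm(3)))
    phi <- axial_twist_angle(a, b)
    mirror <- function(m) m %*% diag(c(-1, 1, 1))
    expect_equal(axial_twist_angle(mirror(a), mirror(b)), -phi,
                 tolerance = 1e-8)
  }
})

test_that("bend and planar angles reproduce the canonical configurations", {
  p <- function(m) make_pair(m, c(0, 0, 1), half_width = 0.3)
  expect_equal(midpoint_bend_angle(p(c(0, 0, 0)), p(c(1, 0, 0)), p(c(2, 0, 0))), 180)
  expect_equal(midpoint_bend_angle(p(c(0, 0, 0)), p(c(1, 0, 0)), p(c(1, 1, 0))), 90)
  expect_equal(midpoint_bend_angle(p(c(0, 0, 0)), p(c(1, 0, 0)),
                                   p(c(0.5, sqrt(3) / 2, 0))), 60)
  expect_error(midpoint_bend_angle(p(c(0, 0, 0)), p(c(0, 0, 0)), p(c(1, 0, 0))),
               "coincide")

  # all six nuclei coplanar: plane angle 0
  q <- function(m, ax) make_pair(m, ax)
  co <- planar_intersection_angle(q(c(0, 0, 0), c(1, 0, 0)),
                                  q(c(0, 3, 0), c(1, 0.2, 0)),
                                  q(c(1, 6, 0), c(1, -0.3, 0) / sqrt(1.09)))
  expect_equal(co, 0, tolerance = 1e-8)
  # second quad orthogonal to the first
  orth <- planar_intersection_angle(q(c(0, 0, 0), c(1, 0, 0)),
                                    q(c(0, 3, 0), c(1, 0, 0)),
                                    q(c(0, 3, 3), c(0, 0, 1)))
  expect_equal(orth, 90)
  expect_error(planar_intersection_angle(q(c(0, 0, 0), c(1, 0, 0)),
                                         q(c(2, 0, 0), c(1, 0, 0)),
                                         q(c(4, 0, 0), c(1, 0, 0))),
               "rank-deficient")
})

test_that("every feature is invariant under rigid motion", {
  set.seed(33)
  for (i in 1:10) {
    Q <- random_rotation(); shift <- rnorm(3, sd = 10)
    a <- make_pair(rnorm(3), .unit3(rnorm(3)), half_width = runif(1, 0.5, 2))
    b <- make_pair(rnorm(3) + c(6, 0, 0), .unit3(rnorm(3)), half_width = runif(1, 0.5, 2))
    c_ <- make_pair(rnorm(3) + c(12, 0, 0), .unit3(rnorm(3)), half_width = runif(1, 0.5, 2))
    ar <- rigid(a, Q, shift); br <- rigid(b, Q, shift); cr <- rigid(c_, Q, shift)
    expect_equal(pair_distance_ratio(ar, br), pair_distance_ratio(a, b))
    expect_equal(midpoint_distance(ar, br), midpoint_distance(a, b))
    expect_equal(side_cosine_similarity(ar, br), side_cosine_similarity(a, b))
    expect_equal(axial_twist_angle(ar, br), axial_twist_angle(a, b))
    expect_equal(lateral_axial_twist_angle(ar, br), lateral_axial_twist_angle(a, b))
    expect_equal(midpoint_bend_angle(ar, br, cr), midpoint_bend_angle(a, b, c_))
    expect_equal(planar_intersection_angle(ar, br, cr),
                 planar_intersection_angle(a, b, c_), tolerance = 1e-6)
  }
})

test_that("angles and lengths stay inside their documented ranges", {
  set.seed(34)
  for (i in 1:50) {
    a <- make_pair(rnorm(3), .unit3(rnorm(3)))
    b <- make_pair(rnorm(3) + c(4, 0, 0), .unit3(rnorm(3)))
    c_ <- make_pair(rnorm(3) + c(8, 0, 0), .unit3(rnorm(3)))
    phi <- axial_twist_angle(a, b)
    expect_true(phi > -180 && phi <= 180)
    tau <- lateral_axial_twist_angle(a, b)
    expect_true(tau >= 0 && tau <= 180)
    th <- midpoint_bend_angle(a, b, c_)
    expect_true(th >= 0 && th <= 180)
    pl <- planar_intersection_angle(a, b, c_)
    expect_true(pl >= 0 && pl <= 90)
    expect_true(abs(side_cosine_similarity(a, b)) <= 1 + 1e-12)
    expect_gte(pair_distance_ratio(a, b), 0)
  }
})

test_that("features vary continuously away from degeneracies", {
  set.seed(35)
  a <- make_pair(c(0, 0, 0), c(1, 0, 0))
  b <- make_pair(c(1, 4, 1), .unit3(c(0.8, 0.1, 0.5)))
  for (eps in c(1e-3, 1e-5, 1e-7)) {
    bp <- b + matrix(eps * rnorm(6), 2L)
    expect_lt(abs(axial_twist_angle(a, bp) - axial_twist_angle(a, b)), 1e4 * eps)
    expect_lt(abs(midpoint_distance(a, bp) - midpoint_distance(a, b)), 10 * eps)
  }
})

test_that("posture-wide sums equal per-position recomputation", {
  # straight untwisted worm: summed twists 0, summed bends 180 (P - 2)
  P <- 5L
  mids <- cbind(seq(0, 40, length.out = P), 0, 0)
  left <- mids + rep(c(0, -2, 0), each = P)
  right <- mids + rep(c(0, 2, 0), each = P)
  po <- labeled_posture(left, right, time = 0.5)
  s <- posture_sum_features(po)
  expect_equal(unname(s["sum_twist_phi"]), 0)
  expect_equal(unname(s["sum_twist_tau"]), 0)
  expect_equal(unname(s["sum_bend_theta"]), 180 * (P - 2))
  expect_equal(unname(s["sum_ratio"]), P - 1)

  # random posture: each sum equals independent per-position recomputation
  set.seed(36)
  cfg <- reduced_worm_config()
  po2 <- generate_posture(cfg, 0.5)
  s2 <- posture_sum_features(po2)
  tf_l <- po2$left[P:1, ]; tf_r <- po2$right[P:1, ]
  pair_at <- function(p) rbind(tf_l[p, ], tf_r[p, ])
  expect_equal(unname(s2["sum_mid_dist"]),
               sum(vapply(1:(P - 1), function(p)
                 midpoint_distance(pair_at(p), pair_at(p + 1)), numeric(1))))
  expect_equal(unname(s2["sum_twist_phi"]),
               sum(vapply(1:(P - 1), function(p)
                 axial_twist_angle(pair_at(p), pair_at(p + 1)), numeric(1))))
  expect_equal(unname(s2["sum_bend_theta"]),
               sum(vapply(1:(P - 2), function(p)
                 midpoint_bend_angle(pair_at(p), pair_at(p + 1), pair_at(p + 2)),
                 numeric(1))))
})
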