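# Template fitting, standardized costs, and model compilation.

test_that("standardized costs are squared z-scores", {
  expect_identical(standardized_cost(3, 3, 1), 0)
  expect_identical(standardized_cost(4, 3, 1, weight = 1), 1)
  expect_identical(standardized_cost(1, 3, 1, weight = 0.5), 2)
  expect_error(standardized_cost(1, 0, 0), "floor")
})

test_that("templates reproduce a constant corpus and interpolate linearly", {
  set.seed(41)
  cfg <- reduced_worm_config(noise_sd = 0)
  po <- generate_posture(cfg, 0.3)
  const_corpus <- lapply(1:3, function(i) list(time = 0.3, posture = po, embryo = i))
  tpl <- fit_templates(const_corpus)
  ft <- posture_feature_table(po)
  for (r in sample(nrow(ft), 10L)) {
    ms <- template_at(tpl, ft$family[r], ft$position[r], 0.3)
    expect_equal(ms$mean, ft$value[r])
    expect_equal(ms$sd, unname(tpl$floors[ft$family[r]]))
  }

  # two time bins: the mean is linear between them
  cfg2 <- reduced_worm_config(noise_sd = 0, n_frames = 2L)
  corpus2 <- corpus_from_series(lapply(1:6, function(i) generate_series(cfg2)))
  tpl2 <- suppressWarnings(fit_templates(corpus2))
  m0 <- template_at(tpl2, "mid_dist", 2L, 0)$mean
  m1 <- template_at(tpl2, "mid_dist", 2L, 1)$mean
  expect_equal(template_at(tpl2, "mid_dist", 2L, 0.5)$mean, (m0 + m1) / 2)
  # constant extrapolation outside the fitted range is clamped
  expect_equal(template_at(tpl2, "mid_dist", 2L, 1)$mean, m1)
})

test_that("fitted means recover the generator's deterministic features", {
  fx <- zero_noise_fixture()
  tpl <- fx$template
  hw <- fx$cfg$half_width_profile
  # lateral distances are deterministic at zero noise: mean = 2 * half width
  for (p in 1:5) {
    ms <- template_at(tpl, "lateral", p, 0.4)
    expect_equal(ms$mean, 2 * rev(hw)[p], tolerance = 1e-9)
  }
  # holdout excludes an embryo without changing the fitted structure
  tpl_h <- suppressWarnings(fit_templates(fx$corpus, holdout = 1L))
  expect_identical(tpl_h$n_pairs, 5L)
  expect_error(fit_templates(list()), "empty corpus")
})

test_that("templates round-trip through their structured-text file", {
  fx <- zero_noise_fixture()
  path <- tempfile(fileext = ".tsv")
  write_template(fx$template, path)
  back <- read_template(path)
  expect_equal(back$n_pairs, fx$template$n_pairs)
  expect_equal(back$table$mean, fx$template$table$mean, tolerance = 1e-12)
  expect_equal(back$table$sd, fx$template$table$sd, tolerance = 1e-12)
  expect_equal(back$floors, fx$template$floors, tolerance = 1e-12)
  unlink(path)
})

test_that("compiled models nest: sides within pairs within posture", {
  fx <- zero_noise_fixture()
  set.seed(42)
  s <- generate_series(fx$cfg)
  fr <- s[[2L]]
  prs <- lapply(c("sides", "pairs", "posture"), function(m)
    build_problem(fr$points, 5L, fx$template, fr$time, model_spec(m)))
  names(prs) <- c("sides", "pairs", "posture")
  expect_identical(max(vapply(prs$sides$tensors, `[[`, integer(1), "degree")), 2L)
  degs_pairs <- vapply(prs$pairs$tensors, `[[`, integer(1), "degree")
  expect_setequal(unique(degs_pairs), c(2L, 4L, 6L))
  full <- prs$posture$tensors[[length(prs$posture$tensors)]]
  expect_identical(full$degree, 10L)
  expect_identical(full$mode, "lazy")

  a <- fr$truth
  o_sides <- evaluate_objective(prs$sides, a)
  o_pairs <- evaluate_objective(prs$pairs, a)
  o_post <- evaluate_objective(prs$posture, a)
  # the higher model's objective is the lower's plus its extra tensors
  extra46 <- sum(vapply(prs$pairs$tensors, function(tn) {
    if (tn$degree <= 2L) return(0)
    sum(vapply(seq_len(nrow(tn$vertex_tuples)), function(r) {
      vt <- tn$vertex_tuples[r, ]
      tn$cost(vt, matrix(a[vt], 1L))
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(o_pairs, o_sides + extra46, tolerance = 1e-9)
  full_cost <- as.numeric(full$cost(full$vertex_tuples[1L, ], matrix(a, 1L)))
  expect_equal(o_post, o_pairs + full_cost, tolerance = 1e-9)

  # sides has no lazy terms: aggregation is identically zero in any search
  d <- decompose_objective(prs$sides, a)
  expect_identical(d$I, rep(0, 5))
})

test_that("a zero-noise posture beats all single-pair perturbations of itself", {
  fx <- zero_noise_fixture()
  set.seed(43)
  s <- generate_series(fx$cfg)
  fr <- s[[3L]]
  for (m in c("pairs", "posture")) {
    pr <- build_problem(fr$points, 5L, fx$template, fr$time, model_spec(m))
    base <- evaluate_objective(pr, fr$truth)
    for (p in 1:5) {
      a <- fr$truth
      a[c(2L * p - 1L, 2L * p)] <- a[c(2L * p, 2L * p - 1L)]
      expect_gt(evaluate_objective(pr, a), base)
    }
    for (p in 1:4) for (q in (p + 1):5) {
      a <- fr$truth
      i <- c(2L * p - 1L, 2L * p); j <- c(2L * q - 1L, 2L * q)
      a[c(i, j)] <- a[c(j, i)]
      expect_gt(evaluate_objective(pr, a), base)
    }
  }
})

test_that("zero-noise truth is the unique optimum of a tiny worm by brute force", {
  set.seed(44)
  cfg <- embryo_sim_config(n_pairs = 3L, body_length_start = 30,
                           body_length_end = 60, noise_sd = 0, n_frames = 3L,
                           coil_curvature_scale = 3)
  corpus <- corpus_from_series(lapply(1:10, function(i) generate_series(cfg)))
  tpl <- suppressWarnings(fit_templates(corpus))
  s <- generate_series(cfg)
  fr <- s[[2L]]
  pr <- build_problem(fr$points, 3L, tpl, fr$time, model_spec("pairs"))
  bf <- brute_force_solve(pr, x = 2L)
  expect_identical(bf$assignments[1L, ], fr$truth)
  expect_gt(bf$costs[2L], bf$costs[1L])
})

test_that("model weights scale their families and reject bad input", {
  expect_error(model_spec("sides", weights = c(ratio = 1)), "included")
  expect_error(model_spec("pairs", weights = c(ratio = -1)), "nonnegative")
  fx <- zero_noise_fixture()
  set.seed(45)
  s <- generate_series(fx$cfg)
  fr <- s[[1L]]
  p1 <- build_problem(fr$points, 5L, fx$template, fr$time, model_spec("sides"))
  spec2 <- model_spec("sides", weights = c(lateral = 2, chord_left = 2,
                                           chord_right = 2))
  p2 <- build_problem(fr$points, 5L, fx$template, fr$time, spec2)
  expect_equal(evaluate_objective(p2, fr$truth),
               2 * evaluate_objective(p1, fr$truth), tolerance = 1e-9)
})

test_that("problem compilation validates its inputs", {
  fx <- zero_noise_fixture()
  pts <- matrix(rnorm(9 * 3), 9L)
  expect_error(build_problem(pts, 5L, fx$template, 0.5), "below n1")
  set.seed(46)
  s <- generate_series(fx$cfg)
  expect_error(build_problem(s[[1L]]$points, 4L, fx$template, 0.5),
               "template was fit")
})
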