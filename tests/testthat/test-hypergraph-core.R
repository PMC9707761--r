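# Core types, objective evaluation, enumeration, and the exhaustive oracle.

test_that("branch step and permutation counts follow the closed forms", {
  expect_identical(count_branch_steps(20, 2), 10L)
  expect_identical(count_branch_steps(22, 2), 11L)
  expect_error(count_branch_steps(6, 4), "divide")

  expect_equal(branch_permutation_count(4, 2), 12)
  expect_equal(branch_permutation_count(7, 2), 42)
  expect_equal(branch_permutation_count(9, 1), 9)
  expect_error(branch_permutation_count(3, 5), "exceed")
})

test_that("tensor constructors enforce the canonical-tuple and sign contracts", {
  expect_error(dissimilarity_tensor(2L, rbind(c(2L, 1L)), function(vt, p) 0),
               "strictly increasing")
  expect_error(table_tensor(1L, rbind(1L), list(c(-1, 0, 1)), 3L),
               "nonnegative")
  # degree <= 2k must be precomputed, higher lazy
  tn_bad <- table_tensor(1L, rbind(1L), list(runif(4)), 4L, mode = "lazy")
  expect_error(matching_problem(2, 4, 2, list(tn_bad)), "precomputed")
  # a lookup outside the stored scope is an error, not a zero
  tn <- table_tensor(1L, rbind(1L), list(runif(4)), 4L)
  expect_error(tn$cost(2L, matrix(1L)), "undefined hyperedge cost")
})

test_that("objective evaluation matches an independent nested-loop summation", {
  # trivial cases
  zero <- table_tensor(1L, matrix(1:3), list(rep(0, 4)), 4L)
  pr0 <- matching_problem(3, 4, 1, list(zero))
  expect_identical(evaluate_objective(pr0, c(2L, 3L, 4L)), 0)

  absdiff <- table_tensor(1L, matrix(1:4),
                          lapply(1:4, function(v) abs(v - 1:4)), 4L)
  pr1 <- matching_problem(4, 4, 1, list(absdiff))
  expect_identical(evaluate_objective(pr1, 1:4), 0)
  expect_error(evaluate_objective(pr1, c(1L, 2L, NA, 4L)), "incomplete")

  # random instance vs a from-scratch loop over the raw cost arrays
  set.seed(101)
  n1 <- 4L; n2 <- 5L
  arrays <- list()
  tensors <- list()
  for (d in c(1L, 2L, 4L)) {
    vts <- t(utils::combn(n1, d))
    vals <- lapply(seq_len(nrow(vts)), function(i) array(runif(n2^d), dim = rep(n2, d)))
    arrays[[as.character(d)]] <- list(vts = vts, vals = vals)
    tensors[[length(tensors) + 1L]] <-
      table_tensor(d, vts, vals, n2, mode = if (d <= 4L) "precomputed" else "lazy")
  }
  pr <- matching_problem(n1, n2, 2L, tensors)
  a <- c(3L, 1L, 5L, 2L)
  oracle <- 0
  for (d in names(arrays)) {
    vts <- arrays[[d]]$vts
    for (r in seq_len(nrow(vts))) {
      idx <- matrix(a[vts[r, ]], nrow = 1L)
      oracle <- oracle + arrays[[d]]$vals[[r]][idx]
    }
  }
  expect_equal(evaluate_objective(pr, a), as.numeric(oracle))
  # determinism: repeated calls are bit-identical
  expect_identical(evaluate_objective(pr, a), evaluate_objective(pr, a))
})

test_that("enumeration yields every injective completion exactly once", {
  pr <- matching_problem(2, 3, 1,
                         list(table_tensor(1L, matrix(1:2), list(rep(0, 3)), 3L)))
  expect_identical(nrow(enumerate_assignments(pr)), 6L)

  pr3 <- matching_problem(3, 3, 1,
                          list(table_tensor(1L, matrix(1:3), list(rep(0, 3)), 3L)))
  seeded <- enumerate_assignments(pr3, c(1L, NA, NA))
  expect_identical(nrow(seeded), 2L)
  expect_true(all(seeded[, 1L] == 1L))
  expect_error(enumerate_assignments(pr3, c(1L, 1L, NA)), "injective")

  # completeness: counts equal the falling factorial for all small sizes
  for (n1 in 1:4) for (n2 in n1:6) {
    p <- matching_problem(n1, n2, 1,
                          list(table_tensor(1L, matrix(seq_len(n1)),
                                            list(rep(0, n2)), n2)))
    A <- enumerate_assignments(p)
    expect_identical(nrow(A), as.integer(branch_permutation_count(n2, n1)))
    expect_identical(nrow(unique(A)), nrow(A))
  }
})

test_that("the brute-force oracle returns the exact lex-ordered top x", {
  set.seed(7)
  pr <- random_instance(4L, 5L, 2L, degrees = c(1L, 2L, 4L))
  bf <- brute_force_solve(pr, x = 3L)
  A <- enumerate_assignments(pr)
  costs <- vapply(seq_len(nrow(A)), function(r) evaluate_objective(pr, A[r, ]),
                  numeric(1))
  expect_equal(bf$costs[1L], min(costs))
  expect_true(all(diff(bf$costs) >= 0))

  # all-zero tensors: any x assignments, all zero cost, in lex order
  z <- matching_problem(2, 3, 1,
                        list(table_tensor(1L, matrix(1:2), list(rep(0, 3)), 3L)))
  bz <- brute_force_solve(z, x = 3L)
  expect_identical(bz$costs, rep(0, 3))
  expect_identical(bz$assignments, rbind(c(1L, 2L), c(1L, 3L), c(2L, 1L)))

  # single feasible completion
  one <- brute_force_solve(pr, seeds = c(2L, 4L, 1L, NA), x = 2L)
  expect_identical(nrow(one$assignments), 2L)
  expect_true(all(one$assignments[, 1L] == 2L))

  big <- matching_problem(10, 12, 1,
                          list(table_tensor(1L, matrix(1:10),
                                            list(rep(0, 12)), 12L)))
  expect_error(brute_force_solve(big), "ehgm_solve")
})

test_that("optimal cost is invariant under relabeling of the points", {
  set.seed(11)
  n1 <- 4L; n2 <- 5L
  vts1 <- matrix(seq_len(n1))
  vals1 <- lapply(seq_len(n1), function(i) runif(n2))
  vts2 <- t(utils::combn(n1, 2L))
  vals2 <- lapply(seq_len(nrow(vts2)), function(i) matrix(runif(n2^2), n2))
  pr <- matching_problem(n1, n2, 2L,
                         list(table_tensor(1L, vts1, vals1, n2),
                              table_tensor(2L, vts2, vals2, n2)))
  sigma <- sample(n2)
  inv <- order(sigma)
  # compose every cost with the relabeling sigma
  vals1p <- lapply(vals1, function(v) v[inv])
  vals2p <- lapply(vals2, function(m) m[inv, inv])
  prp <- matching_problem(n1, n2, 2L,
                          list(table_tensor(1L, vts1, vals1p, n2),
                               table_tensor(2L, vts2, vals2p, n2)))
  expect_equal(brute_force_solve(pr, x = 1L)$costs,
               brute_force_solve(prp, x = 1L)$costs)
})

test_that("problem dumps list every in-scope hyperedge with its cost", {
  set.seed(3)
  pr <- random_instance(4L, 4L, 2L, degrees = c(1L, 2L))
  a <- c(2L, 1L, 4L, 3L)
  lines <- dump_problem(pr, a, file = nullfile())
  expect_identical(length(lines), 4L + 6L)
  total <- sum(vapply(strsplit(lines, "\t"), function(p) as.numeric(p[4L]),
                      numeric(1)))
  expect_equal(total, evaluate_objective(pr, a), tolerance = 1e-9)
})
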