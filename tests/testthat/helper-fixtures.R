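# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Zero-noise reduced worm with a template fit from its own generator corpus.
zero_noise_fixture <- function() {
  if (is.null(.fixtures$zn)) {
    set.seed(4242)
    cfg <- reduced_worm_config(noise_sd = 0)
    corpus <- corpus_from_series(lapply(1:12, function(i) generate_series(cfg)))
    template <- suppressWarnings(fit_templates(corpus))
    .fixtures$zn <- list(cfg = cfg, corpus = corpus, template = template)
  }
  .fixtures$zn
}

# A random small problem exercising precomputed and lazy tensor degrees.
random_instance <- function(n1 = 6L, n2 = 7L, k = 2L, degrees = c(1L, 2L, 4L, 6L)) {
  random_matching_problem(n1, n2, k, degrees)
}

# A uniformly random proper rotation matrix.
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# Apply a rigid motion to a 2 x 3 pair matrix (or any n x 3 matrix).
rigid <- function(m, Q, shift) m %*% Q + rep(shift, each = nrow(m))

# A simple synthetic pair at a midpoint with a given axis direction.
make_pair <- function(mid, axis, half_width = 1) {
  rbind(mid - half_width * axis, mid + half_width * axis)
}

.unit3 <- function(v) v / sqrt(sum(v^2))

expect_pool_equal <- function(a, b) {
  expect_equal(as.numeric(a$costs), as.numeric(b$costs))
  expect_identical(a$assignments, b$assignments)
}
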