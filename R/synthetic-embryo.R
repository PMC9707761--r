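# Synthetic coiled-embryo generator.  Emulates the statistical structure
# the posture models assume: bilaterally paired nuclei along a smooth
# coiled 3-D backbone, a thin near-constant-width tail leading to a
# thicker body, elongation over development with locally straightening
# bends, and complete repositioning between frames.  All randomness uses
# R's global RNG stream (set.seed for determinism).

#' Simulator configuration
#'
#' Defaults are simulator conventions chosen to loosely mirror late-stage
#' embryo biology (not measurements of any specific dataset): 10 bilateral
#' pairs, body elongating from 60 to 170 micrometers across development, a
#' constant-width tail pair, and isotropic Gaussian nucleus jitter.
#'
#' @param n_pairs Number of bilateral pairs (10 pre-Q, 11 post-Q, or fewer
#'   for reduced test worms).
#' @param body_length_start,body_length_end Backbone arclength in
#'   micrometers at normalized times 0 and 1.
#' @param tail_width Lateral width of the tail pair (micrometers),
#'   constant across development.
#' @param half_width_profile Optional numeric vector (length `n_pairs`,
#'   anterior to posterior) of lateral half-widths in micrometers; the
#'   default tapers from a thicker mid-body to `tail_width / 2` at T.
#' @param coil_curvature_scale Total bend of the backbone heading at
#'   `t = 0`, in radians; 0 gives a straight body.  The effective bend
#'   shrinks with development (halved by `t = 1`) so bend angles
#'   straighten locally as the body elongates.
#' @param torsion_drift Mean station-to-station twist (radians) of the
#'   left-right axis about the backbone.  A nonzero drift gives the body a
#'   consistent handedness, as in a real coiled embryo; it is what makes
#'   mirror postures distinguishable through the signed twist angle.
#' @param torsion_scale Standard deviation (radians) of the random
#'   station-to-station twist around the drift.
#' @param noise_sd Isotropic Gaussian jitter per nucleus (micrometers).
#' @param n_frames Frames per developmental series.
#' @return Object of class `embryo_sim_config`.
#' @export
embryo_sim_config <- function(n_pairs = 10L,
                              body_length_start = 60,
                              body_length_end = 170,
                              tail_width = 5,
                              half_width_profile = NULL,
                              coil_curvature_scale = 5,
                              torsion_drift = 0.3,
                              torsion_scale = 0.15,
                              noise_sd = 0.5,
                              n_frames = 8L) {
  n_pairs <- as.integer(n_pairs)
  if (is.null(half_width_profile)) {
    # smooth taper, thicker mid-body; widths are close but not exactly
    # equal anywhere, as in a real body
    u <- seq(0, 1, length.out = n_pairs) # anterior -> posterior
    half_width_profile <- stats::approx(x = c(0, 0.25, 0.55, 0.8, 1),
                                        y = c(3.5, 4.7, 5.1, 4.2, tail_width / 2),
                                        xout = u)$y
  }
  stopifnot(length(half_width_profile) == n_pairs,
            all(half_width_profile > 0), tail_width > 0,
            body_length_start > 0,
            body_length_end >= body_length_start,
            coil_curvature_scale >= 0, torsion_scale >= 0, noise_sd >= 0,
            n_frames >= 1L)
  half_width_profile[n_pairs] <- tail_width / 2
  structure(list(n_pairs = n_pairs,
                 body_length_start = body_length_start,
                 body_length_end = body_length_end,
                 tail_width = tail_width,
                 half_width_profile = half_width_profile,
                 coil_curvature_scale = coil_curvature_scale,
                 torsion_drift = torsion_drift,
                 torsion_scale = torsion_scale,
                 noise_sd = noise_sd,
                 n_frames = as.integer(n_frames)),
            class = "embryo_sim_config")
}

#' Sample a smooth coiled backbone
#'
#' Draws a near-planar spiral coil: the heading turns through a total bend
#' of `coil_curvature_scale * (1 - 0.5 t)` radians (the body straightens
#' locally as it elongates), with a smooth random modulation of the local
#' curvature along the body, a smooth out-of-plane wobble interpolated by
#' natural cubic splines through random control values, and exact
#' arclength `L(t) = length_start + t * (length_end - length_start)`.
#' The curvature keeps one sign, as for an embryo spiralling inside the
#' eggshell; together with the handed twist of the left-right axis this
#' places one seam row consistently toward the inside of the coil at each
#' body position, the asymmetry that renders left and right
#' distinguishable.  Curves whose distant stations come closer than twice
#' the maximum body width are rejection-resampled.
#'
#' @param config An [embryo_sim_config()].
#' @param t Normalized developmental time in `[0, 1]`.
#' @param n_samples Number of equally spaced arclength stations returned.
#' @return Object of class `embryo_backbone`: list with `points`
#'   (`n_samples x 3`, equally spaced in arclength), `tangent`, `normal`
#'   (parallel-transported unit frames), and `length` (micrometers).
#' @export
sample_backbone <- function(config, t, n_samples = 200L) {
  stopifnot(inherits(config, "embryo_sim_config"), t >= 0, t <= 1)
  L <- config$body_length_start +
    t * (config$body_length_end - config$body_length_start)
  turn <- config$coil_curvature_scale * (1 - 0.5 * t)
  max_hw <- max(config$half_width_profile)
  nc <- 9L
  s0 <- seq(0, 1, length.out = n_samples)
  sc <- seq(0, 1, length.out = nc)
  ds <- L / (n_samples - 1L)
  P <- NULL
  for (try in seq_len(60L)) {
    # smooth positive curvature modulation, normalized to the total bend
    g <- exp(stats::spline(sc, stats::rnorm(nc, sd = 0.5), xout = s0,
                           method = "natural")$y)
    kappa <- turn * g / (sum(g) * ds)
    heading <- cumsum(kappa * ds)
    xy <- cbind(cumsum(cos(heading) * ds), cumsum(sin(heading) * ds))
    # out-of-plane wobble, vanishing with the coil amplitude
    zamp <- 0.4 * turn
    z <- zamp * stats::spline(sc, stats::rnorm(nc), xout = s0,
                              method = "natural")$y
    P <- cbind(rbind(0, xy)[seq_len(n_samples), ], z)
    seglen <- .row_norm(diff(P))
    arc <- c(0, cumsum(seglen))
    target <- seq(0, arc[n_samples], length.out = n_samples)
    P <- vapply(1:3, function(d) stats::approx(arc, P[, d], xout = target)$y,
                numeric(n_samples))
    P <- P * (L / arc[n_samples])
    if (turn == 0 || !.self_intersects(P, L, 2 * max_hw))
      return(.backbone_with_frames(P, L))
  }
  warning("backbone self-intersection persisted after 60 resamples; using last draw")
  .backbone_with_frames(P, L)
}

# Distant-station proximity check on a thinned copy of the curve.
.self_intersects <- function(P, L, min_clearance) {
  n <- nrow(P)
  thin <- P[seq(1L, n, by = 4L), , drop = FALSE]
  m <- nrow(thin)
  step <- L / (m - 1)
  d <- as.matrix(stats::dist(thin))
  sep <- abs(outer(seq_len(m), seq_len(m), "-")) * step
  any(d[sep > 2 * min_clearance] < min_clearance)
}

.backbone_with_frames <- function(P, L) {
  n <- nrow(P)
  tang <- rbind(P[2L, ] - P[1L, ],
                (P[3:n, , drop = FALSE] - P[1:(n - 2L), , drop = FALSE]) / 2,
                P[n, ] - P[n - 1L, ])
  tang <- tang / .row_norm(tang)
  normal <- matrix(0, n, 3L)
  ref <- c(0, 0, 1)
  if (abs(sum(ref * tang[1L, ])) > 0.9) ref <- c(0, 1, 0)
  v <- ref - sum(ref * tang[1L, ]) * tang[1L, ]
  normal[1L, ] <- v / sqrt(sum(v^2))
  for (i in 2:n) { # parallel transport
    v <- normal[i - 1L, ] - sum(normal[i - 1L, ] * tang[i, ]) * tang[i, ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) v <- .any_perp(tang[i, ]) else v <- v / nv
    normal[i, ] <- v
  }
  structure(list(points = P, tangent = tang, normal = normal, length = L),
            class = "embryo_backbone")
}

.any_perp <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v / sqrt(sum(v^2))
}

#' Generate one labeled synthetic posture
#'
#' Places pair midpoints equally spaced in arclength along a freshly
#' sampled backbone (anterior at arclength 0, the tail pair at the
#' posterior end), offsets left/right nuclei by the per-position
#' half-width along the local (torsion-twisted) normal, and adds isotropic
#' Gaussian jitter.
#'
#' @inheritParams sample_backbone
#' @return A [labeled_posture()] at time `t`.
#' @export
generate_posture <- function(config, t) {
  P <- config$n_pairs
  bb <- sample_backbone(config, t)
  n <- nrow(bb$points)
  idx <- round(seq(1L, n, length.out = P))
  twist <- config$torsion_drift * seq_len(P) +
    config$torsion_scale * cumsum(stats::rnorm(P))
  left <- matrix(0, P, 3L); right <- matrix(0, P, 3L)
  for (p in seq_len(P)) {
    i <- idx[p]
    axis <- .rotate_about(bb$normal[i, ], bb$tangent[i, ], twist[p])
    hw <- config$half_width_profile[p]
    left[p, ] <- bb$points[i, ] - hw * axis
    right[p, ] <- bb$points[i, ] + hw * axis
  }
  if (config$noise_sd > 0) {
    left <- left + matrix(stats::rnorm(3L * P, sd = config$noise_sd), P, 3L)
    right <- right + matrix(stats::rnorm(3L * P, sd = config$noise_sd), P, 3L)
  }
  # random rigid repositioning: all model features are rigid-invariant,
  # but raw coordinates should differ completely between frames
  Q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  shift <- stats::rnorm(3L, sd = 20)
  left <- left %*% Q + rep(shift, each = P)
  right <- right %*% Q + rep(shift, each = P)
  labeled_posture(left, right, time = t)
}

# Rodrigues rotation of v about unit axis u by angle theta (radians).
.rotate_about <- function(v, u, theta) {
  v * cos(theta) +
    c(u[2] * v[3] - u[3] * v[2],
      u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1]) * sin(theta) +
    u * sum(u * v) * (1 - cos(theta))
}

#' Shuffle a posture into an unlabeled point-set with ground truth
#'
#' Applies a uniformly random permutation to the branch-ordered nuclei
#' (tail-first, left before right within each pair) and returns the
#' shuffled coordinates together with the assignment that inverts the
#' shuffle: `points[truth[v], ]` is the coordinate of branch-order vertex
#' `v`.
#'
#' @param posture A [labeled_posture()].
#' @return List with `points` (an `n1 x 3` matrix) and `truth` (an integer
#'   assignment of length `n1`).
#' @export
strip_labels <- function(posture) {
  V <- posture_vertices(posture)
  n1 <- nrow(V)
  perm <- sample.int(n1)
  points <- V[order(perm), , drop = FALSE]
  dimnames(points) <- NULL
  list(points = points, truth = perm)
}

#' Generate a developmental series of synthetic frames
#'
#' One posture per frame at `t = (frame - 1) / (n_frames - 1)` (a single
#' frame sits at `t = 0`).  Each frame's backbone is resampled
#' independently — the embryo completely repositions between frames, the
#' regime that defeats coherent-transform matchers — while the width and
#' elongation profiles stay fixed.  Each frame carries the labeled
#' posture, the shuffled unlabeled point list, and the ground-truth
#' assignment.
#'
#' @param config An [embryo_sim_config()].
#' @return Object of class `synthetic_series`: list of frames, each with
#'   elements `time`, `posture`, `points`, `truth`.
#' @export
generate_series <- function(config) {
  nf <- config$n_frames
  frames <- lapply(seq_len(nf), function(f) {
    t <- if (nf == 1L) 0 else (f - 1) / (nf - 1)
    posture <- generate_posture(config, t)
    sh <- strip_labels(posture)
    list(time = t, posture = posture, points = sh$points, truth = sh$truth)
  })
  structure(frames, class = "synthetic_series")
}

#' @export
print.synthetic_series <- function(x, ...) {
  cat("Synthetic embryo series:", length(x), "frame(s),",
      nrow(x[[1L]]$posture$left), "pairs\n")
  invisible(x)
}

#' Build a template-fitting corpus from synthetic series
#'
#' Flattens one or more synthetic series into the sample list accepted by
#' [fit_templates()], tagging each sample with its embryo id.
#'
#' @param series_list List of [generate_series()] results (one per
#'   simulated embryo).
#' @param embryo_ids Optional ids (default `1..length(series_list)`).
#' @return Corpus list of `(time, posture, embryo)` samples.
#' @export
corpus_from_series <- function(series_list, embryo_ids = seq_along(series_list)) {
  if (inherits(series_list, "synthetic_series")) series_list <- list(series_list)
  out <- list()
  for (i in seq_along(series_list)) {
    for (fr in series_list[[i]]) {
      out[[length(out) + 1L]] <- list(time = fr$time, posture = fr$posture,
                                      embryo = embryo_ids[[i]])
    }
  }
  out
}

#' Reduced simulator preset for oracle-verified tests
#'
#' A 5-pair worm (`n1 = 10`) with the default geometry otherwise; small
#' enough that end-to-end searches finish in seconds while exercising
#' every tensor degree.
#'
#' @param ... Overrides passed to [embryo_sim_config()].
#' @return An [embryo_sim_config()].
#' @export
reduced_worm_config <- function(...) {
  args <- list(...)
  defaults <- list(n_pairs = 5L, body_length_start = 40, body_length_end = 90,
                   tail_width = 5, n_frames = 4L)
  defaults[names(args)] <- args
  do.call(embryo_sim_config, defaults)
}
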