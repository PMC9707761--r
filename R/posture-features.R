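# Geometric features of seam-cell postures.  A "pair" is one bilateral
# pair of nuclei, passed as a 2 x 3 matrix (row 1 the left nucleus, row 2
# the right, coordinates in micrometers).  Angles are reported in degrees;
# unsigned angles lie in [0, 180] unless documented otherwise.
#
# Feature arguments follow branch order: pair_i is posterior to pair_j
# (the search assigns pairs tail-first).

.pair_lr <- function(pair) {
  pair <- as.matrix(pair)
  if (!all(dim(pair) == c(2L, 3L)))
    stop("a pair must be a 2 x 3 matrix (rows: left, right nucleus)")
  storage.mode(pair) <- "double"
  pair
}

#' Distance between the nuclei of a lateral pair
#'
#' @param left,right Length-3 coordinate vectors (micrometers).
#' @return Euclidean distance (micrometers).
#' @examples
#' lateral_pair_distance(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
lateral_pair_distance <- function(left, right) {
  .row_norm(.as_row3(right) - .as_row3(left))
}

#' Chord length between two nuclei along one side of the body
#'
#' Same geometry as [lateral_pair_distance()] but a distinct model role:
#' sequential chords along the left and right sides are the edge features
#' of the Sides model.
#'
#' @param a,b Length-3 coordinate vectors (micrometers).
#' @return Euclidean distance (micrometers).
#' @export
side_chord_length <- function(a, b) {
  .row_norm(.as_row3(b) - .as_row3(a))
}

#' Ratio of lateral pair distances of two successive pairs
#'
#' The posterior pair's width is the numerator (pairs are taken in branch
#' order, tail first).
#'
#' @param pair_i Posterior pair (2 x 3 matrix, rows left/right).
#' @param pair_j Next (more anterior) pair.
#' @return Positive ratio.
#' @export
pair_distance_ratio <- function(pair_i, pair_j) {
  pi_ <- .pair_lr(pair_i); pj <- .pair_lr(pair_j)
  den <- lateral_pair_distance(pj[1L, ], pj[2L, ])
  if (den <= 0) stop("degenerate pair: zero lateral distance in the denominator")
  lateral_pair_distance(pi_[1L, ], pi_[2L, ]) / den
}

#' Distance between the midpoints of two successive pairs
#'
#' @inheritParams pair_distance_ratio
#' @return Euclidean distance (micrometers).
#' @export
midpoint_distance <- function(pair_i, pair_j) {
  pi_ <- .pair_lr(pair_i); pj <- .pair_lr(pair_j)
  .row_norm(.as_row3(colMeans(pj)) - .as_row3(colMeans(pi_)))
}

#' Cosine similarity between side chords
#'
#' With two pairs, compares the left-side chord with the right-side chord
#' of the same body segment: the cosine of the angle between the vector
#' from the left nucleus of `pair_i` to the left nucleus of `pair_j` and
#' the corresponding right-side vector (one value; the model default).
#' With a third pair, compares each side's chord with its own next chord
#' and returns `c(cos_left, cos_right)`.
#'
#' @inheritParams pair_distance_ratio
#' @param pair_k Optional third (most anterior) pair; switches to the
#'   successive-chord comparison.
#' @return One cosine in `[-1, 1]`, or two when `pair_k` is given.
#' @export
side_cosine_similarity <- function(pair_i, pair_j, pair_k = NULL) {
  pi_ <- .pair_lr(pair_i); pj <- .pair_lr(pair_j)
  lij <- .as_row3(pj[1L, ] - pi_[1L, ])
  rij <- .as_row3(pj[2L, ] - pi_[2L, ])
  if (is.null(pair_k)) {
    u <- .row_unit(lij, "left side chord")
    v <- .row_unit(rij, "right side chord")
    return(as.numeric(.row_dot(u, v)))
  }
  pk <- .pair_lr(pair_k)
  ljk <- .as_row3(pk[1L, ] - pj[1L, ])
  rjk <- .as_row3(pk[2L, ] - pj[2L, ])
  c(cos_left = as.numeric(.row_dot(.row_unit(lij, "left side chord"),
                                   .row_unit(ljk, "left side chord"))),
    cos_right = as.numeric(.row_dot(.row_unit(rij, "right side chord"),
                                    .row_unit(rjk, "right side chord"))))
}

#' Signed axial twist angle between two successive pairs
#'
#' The signed dihedral angle between the two pair axes (left-to-right
#' vectors) about the chord joining the pair midpoints, in `(-180, 180]`
#' degrees.  The sign is chirality-sensitive: it flips under mirror
#' reflection, which is what lets posture models distinguish mirrored
#' postures.
#'
#' @inheritParams pair_distance_ratio
#' @return Signed angle in degrees.
#' @export
axial_twist_angle <- function(pair_i, pair_j) {
  pi_ <- .pair_lr(pair_i); pj <- .pair_lr(pair_j)
  a1 <- .as_row3(pi_[2L, ] - pi_[1L, ])
  a2 <- .as_row3(pj[2L, ] - pj[1L, ])
  if (any(.row_norm(a1) <= 0) || any(.row_norm(a2) <= 0))
    stop("degenerate pair axis (zero length)")
  chord <- .as_row3(colMeans(pj) - colMeans(pi_))
  if (any(.row_norm(chord) <= 0)) stop("degenerate midpoint chord (zero length)")
  as.numeric(.row_dihedral(a1, a2, chord))
}

#' Lateral axial twist angle between two successive pairs
#'
#' The unprojected angle between the two pair axes, in `[0, 180]` degrees.
#'
#' @inheritParams pair_distance_ratio
#' @return Angle in degrees.
#' @export
lateral_axial_twist_angle <- function(pair_i, pair_j) {
  pi_ <- .pair_lr(pair_i); pj <- .pair_lr(pair_j)
  a1 <- .as_row3(pi_[2L, ] - pi_[1L, ])
  a2 <- .as_row3(pj[2L, ] - pj[1L, ])
  if (any(.row_norm(a1) <= 0) || any(.row_norm(a2) <= 0))
    stop("degenerate pair axis (zero length)")
  as.numeric(.row_angle(a1, a2))
}

#' Bend angle at the middle of three successive pair midpoints
#'
#' The interior angle at `pair_j`'s midpoint between the chords to the
#' midpoints of `pair_i` and `pair_k`, in `[0, 180]` degrees; 180 for
#' collinear midpoints (a locally straight body).
#'
#' @inheritParams side_cosine_similarity
#' @return Angle in degrees.
#' @export
midpoint_bend_angle <- function(pair_i, pair_j, pair_k) {
  m1 <- colMeans(.pair_lr(pair_i))
  m2 <- colMeans(.pair_lr(pair_j))
  m3 <- colMeans(.pair_lr(pair_k))
  u <- .as_row3(m1 - m2); v <- .as_row3(m3 - m2)
  if (any(.row_norm(u) <= 0) || any(.row_norm(v) <= 0))
    stop("coincident midpoints: bend angle undefined")
  as.numeric(.row_angle(u, v))
}

#' Angle between the best-fit planes of successive pair quads
#'
#' Fits a total-least-squares plane to the four nuclei of
#' `pair_i` + `pair_j` and another to `pair_j` + `pair_k`, and returns the
#' angle between the two plane normals folded into `[0, 90]` degrees
#' (plane orientation is arbitrary).
#'
#' @inheritParams side_cosine_similarity
#' @return Angle in degrees, in `[0, 90]`.
#' @export
planar_intersection_angle <- function(pair_i, pair_j, pair_k) {
  pi_ <- .pair_lr(pair_i); pj <- .pair_lr(pair_j); pk <- .pair_lr(pair_k)
  n1 <- .plane_normal(rbind(pi_, pj))
  n2 <- .plane_normal(rbind(pj, pk))
  ang <- .row_angle(.as_row3(n1), .as_row3(n2))
  as.numeric(pmin(ang, 180 - ang))
}

# ---- labeled postures ------------------------------------------------------

#' Canonical seam-cell pair names
#'
#' Pairs anterior to posterior: `H0 H1 H2 V1 V2 V3 V4 V5 [Q] V6 T`.  The Q
#' neuroblast pair is present only post-Q (`n_pairs = 11`).  For reduced
#' test worms (`n_pairs < 10`) the tail-anchored suffix of the pre-Q
#' ordering is used, so the tail pair `T` is always present.
#'
#' @param n_pairs Number of bilateral pairs (10 pre-Q, 11 post-Q, or fewer
#'   for reduced worms).
#' @return Character vector of pair names, anterior to posterior.
#' @export
seam_pair_names <- function(n_pairs) {
  pre <- c("H0", "H1", "H2", "V1", "V2", "V3", "V4", "V5", "V6", "T")
  post <- c("H0", "H1", "H2", "V1", "V2", "V3", "V4", "V5", "Q", "V6", "T")
  n_pairs <- as.integer(n_pairs)
  if (n_pairs == 11L) return(post)
  if (n_pairs < 2L || n_pairs > 10L) stop("n_pairs must be in 2..11")
  pre[(10L - n_pairs + 1L):10L]
}

#' Construct a labeled posture
#'
#' A posture is the joint identification of all seam-cell (and, post-Q,
#' neuroblast) nuclei: bilateral pairs ordered anterior to posterior, each
#' with a left and right nucleus coordinate in micrometers, plus a
#' normalized developmental time.
#'
#' @param left,right Numeric `n_pairs x 3` coordinate matrices, rows
#'   anterior to posterior.
#' @param time Normalized developmental time in `[0, 1]`.
#' @param names Pair names; defaults to [seam_pair_names()].
#' @return Object of class `labeled_posture`.
#' @export
labeled_posture <- function(left, right, time,
                            names = seam_pair_names(nrow(left))) {
  left <- as.matrix(left); right <- as.matrix(right)
  stopifnot(ncol(left) == 3L, ncol(right) == 3L,
            nrow(left) == nrow(right), nrow(left) >= 2L,
            is.numeric(time), length(time) == 1L, time >= 0, time <= 1)
  if (!all(is.finite(left)) || !all(is.finite(right)))
    stop("all nucleus coordinates must be finite")
  if (!identical(names, seam_pair_names(nrow(left))))
    stop("pair names must be the canonical anterior-to-posterior ordering")
  all_pts <- rbind(left, right)
  if (anyDuplicated(all_pts)) stop("no two nuclei may coincide")
  structure(list(names = names, left = left, right = right, time = time),
            class = "labeled_posture")
}

#' @export
print.labeled_posture <- function(x, ...) {
  cat("Labeled posture:", nrow(x$left), "pairs (",
      paste(x$names[1], "...", x$names[length(x$names)]),
      "), t =", format(x$time, digits = 3), "\n")
  invisible(x)
}

# Tail-first (branch order) views of a posture.
.tail_first <- function(posture) {
  P <- nrow(posture$left)
  idx <- P:1
  list(left = posture$left[idx, , drop = FALSE],
       right = posture$right[idx, , drop = FALSE],
       names = posture$names[idx], P = P)
}

# Vertex coordinates in branch order: (T_L, T_R, V6_L, V6_R, ...).
posture_vertices <- function(posture) {
  tf <- .tail_first(posture)
  V <- matrix(0, 2L * tf$P, 3L)
  V[seq(1L, by = 2L, length.out = tf$P), ] <- tf$left
  V[seq(2L, by = 2L, length.out = tf$P), ] <- tf$right
  rownames(V) <- as.vector(rbind(paste0(tf$names, "L"), paste0(tf$names, "R")))
  V
}

# Batch features of a sequence of segments: inputs are n x 3 coordinate
# matrices for the posterior pair (L1, R1) and anterior pair (L2, R2) of
# each segment (one segment per row).
.quad_features <- function(L1, R1, L2, R2) {
  a1 <- R1 - L1
  a2 <- R2 - L2
  d1 <- .row_norm(a1); d2 <- .row_norm(a2)
  if (any(d1 <= 0) || any(d2 <= 0)) stop("degenerate pair: zero lateral distance")
  m1 <- (L1 + R1) / 2; m2 <- (L2 + R2) / 2
  chord <- m2 - m1
  lij <- L2 - L1; rij <- R2 - R1
  list(ratio = d1 / d2,
       mid_dist = .row_norm(chord),
       cos_sides = .row_dot(.row_unit(lij, "left side chord"),
                            .row_unit(rij, "right side chord")),
       twist_phi = .row_dihedral(a1, a2, chord),
       twist_tau = .row_angle(a1, a2))
}

# Batch features of pair triplets (bend + planar angle), one triplet/row.
.six_features <- function(L1, R1, L2, R2, L3, R3) {
  m1 <- (L1 + R1) / 2; m2 <- (L2 + R2) / 2; m3 <- (L3 + R3) / 2
  u <- m1 - m2; v <- m3 - m2
  if (any(.row_norm(u) <= 0) || any(.row_norm(v) <= 0))
    stop("coincident midpoints: bend angle undefined")
  n <- nrow(L1)
  planar <- numeric(n)
  for (i in seq_len(n)) {
    n1 <- .plane_normal(rbind(L1[i, ], R1[i, ], L2[i, ], R2[i, ]))
    n2 <- .plane_normal(rbind(L2[i, ], R2[i, ], L3[i, ], R3[i, ]))
    a <- .row_angle(.as_row3(n1), .as_row3(n2))
    planar[i] <- min(a, 180 - a)
  }
  list(bend_theta = .row_angle(u, v), planar = planar)
}

#' All feature families of one posture
#'
#' Computes every model feature family on a labeled posture, with body
#' positions indexed from the tail (position 1 is the T pair, or the
#' segment/triplet anchored at T), matching the solver's branch order.
#'
#' @param posture A [labeled_posture()].
#' @return Data frame with columns `family`, `position`, `value`.
#' @export
posture_feature_table <- function(posture) {
  tf <- .tail_first(posture)
  P <- tf$P
  L <- tf$left; R <- tf$right
  seg <- seq_len(P - 1L)          # segments (p, p+1), tail-first
  tri <- seq_len(max(P - 2L, 0L)) # triplets (p, p+1, p+2)

  lat <- .row_norm(R - L)
  chord_l <- .row_norm(L[seg + 1L, , drop = FALSE] - L[seg, , drop = FALSE])
  chord_r <- .row_norm(R[seg + 1L, , drop = FALSE] - R[seg, , drop = FALSE])
  q <- .quad_features(L[seg, , drop = FALSE], R[seg, , drop = FALSE],
                      L[seg + 1L, , drop = FALSE], R[seg + 1L, , drop = FALSE])
  s <- .six_features(L[tri, , drop = FALSE], R[tri, , drop = FALSE],
                     L[tri + 1L, , drop = FALSE], R[tri + 1L, , drop = FALSE],
                     L[tri + 2L, , drop = FALSE], R[tri + 2L, , drop = FALSE])

  rows <- rbind(
    data.frame(family = "lateral", position = seq_len(P), value = lat),
    data.frame(family = "chord_left", position = seg, value = chord_l),
    data.frame(family = "chord_right", position = seg, value = chord_r),
    data.frame(family = "ratio", position = seg, value = q$ratio),
    data.frame(family = "mid_dist", position = seg, value = q$mid_dist),
    data.frame(family = "cos_sides", position = seg, value = q$cos_sides),
    data.frame(family = "twist_phi", position = seg, value = q$twist_phi),
    data.frame(family = "twist_tau", position = seg, value = q$twist_tau),
    data.frame(family = "bend_theta", position = tri, value = s$bend_theta),
    data.frame(family = "planar", position = tri, value = s$planar))
  sums <- posture_sum_features(posture)
  rbind(rows, data.frame(family = names(sums), position = 1L, value = unname(sums)))
}

#' Posture-wide summed features
#'
#' For each pair-level feature family of the Pairs model, the sum of that
#' feature over all consecutive body positions: one scalar per family.
#' These are the maximum-degree features the Posture model evaluates
#' jointly over a complete assignment.
#'
#' @param posture A [labeled_posture()].
#' @return Named numeric vector: `sum_ratio`, `sum_mid_dist`,
#'   `sum_cos_sides`, `sum_twist_phi`, `sum_twist_tau`, `sum_bend_theta`,
#'   `sum_planar`.
#' @export
posture_sum_features <- function(posture) {
  tf <- .tail_first(posture)
  P <- tf$P; L <- tf$left; R <- tf$right
  seg <- seq_len(P - 1L)
  tri <- seq_len(max(P - 2L, 0L))
  q <- .quad_features(L[seg, , drop = FALSE], R[seg, , drop = FALSE],
                      L[seg + 1L, , drop = FALSE], R[seg + 1L, , drop = FALSE])
  s <- .six_features(L[tri, , drop = FALSE], R[tri, , drop = FALSE],
                     L[tri + 1L, , drop = FALSE], R[tri + 1L, , drop = FALSE],
                     L[tri + 2L, , drop = FALSE], R[tri + 2L, , drop = FALSE])
  c(sum_ratio = sum(q$ratio),
    sum_mid_dist = sum(q$mid_dist),
    sum_cos_sides = sum(q$cos_sides),
    sum_twist_phi = sum(q$twist_phi),
    sum_twist_tau = sum(q$twist_tau),
    sum_bend_theta = sum(s$bend_theta),
    sum_planar = sum(s$planar))
}
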