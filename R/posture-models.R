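# Time-dependent posture templates and the compilation of the Sides,
# Pairs, and Posture models into hypergraph matching problems.

# Feature families by model and hyperedge degree.  Degree "full" denotes
# the maximum-degree (d = n1) posture-wide families.
.family_degree <- c(lateral = 2, chord_left = 2, chord_right = 2,
                    ratio = 4, mid_dist = 4, cos_sides = 4,
                    twist_phi = 4, twist_tau = 4,
                    bend_theta = 6, planar = 6,
                    sum_ratio = NA, sum_mid_dist = NA, sum_cos_sides = NA,
                    sum_twist_phi = NA, sum_twist_tau = NA,
                    sum_bend_theta = NA, sum_planar = NA)

.sides_families <- c("lateral", "chord_left", "chord_right")
.pairs_families <- c(.sides_families,
                     "ratio", "mid_dist", "cos_sides", "twist_phi", "twist_tau",
                     "bend_theta", "planar")
.sum_families <- c("sum_ratio", "sum_mid_dist", "sum_cos_sides",
                   "sum_twist_phi", "sum_twist_tau", "sum_bend_theta",
                   "sum_planar")

#' Posture model specification
#'
#' The three models trade modeling capacity against computation:
#' \describe{
#'   \item{sides}{Graphical (degree-2 only): standardized lateral pair
#'     distances plus sequential chord lengths along each side.}
#'   \item{pairs}{Adds degree-4 hyperedges on sequential pairs (distance
#'     ratio, midpoint distance, side-chord cosine, signed and lateral
#'     twist angles) and degree-6 hyperedges on sequential triplets
#'     (midpoint bend angle, planar intersection angle).}
#'   \item{posture}{Additionally evaluates all assignments jointly through
#'     one maximum-degree hyperedge carrying posture-wide sums of the
#'     pair-level features.}
#' }
#'
#' @param name One of `"sides"`, `"pairs"`, `"posture"`.
#' @param weights Optional named numeric vector of per-family weights
#'   (default 1 for every included family).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name = c("posture", "pairs", "sides"), weights = NULL) {
  name <- match.arg(name)
  fams <- switch(name,
                 sides = .sides_families,
                 pairs = .pairs_families,
                 posture = c(.pairs_families, .sum_families))
  w <- stats::setNames(rep(1, length(fams)), fams)
  if (!is.null(weights)) {
    if (is.null(names(weights)) || !all(names(weights) %in% fams))
      stop("weights must be named after included feature families")
    if (any(weights < 0)) stop("weights must be nonnegative")
    w[names(weights)] <- weights
  }
  structure(list(name = name, families = fams, weights = w),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Posture model '", x$name, "': ", length(x$families),
      " feature families\n", sep = "")
  invisible(x)
}

# ---- template fitting ------------------------------------------------------

#' Fit a time-dependent posture template from a labeled corpus
#'
#' For every feature family and body position, estimates the mean and
#' standard deviation of the feature as piecewise-linear functions of
#' normalized developmental time, with knots at the deciles of the
#' observed times.  Samples are pooled into the nearest knot's bin; a bin
#' with fewer than two samples borrows the family's corpus-wide sd (with a
#' warning).  Standard deviations are floored at a small positive epsilon
#' per family so standardized costs stay finite.
#'
#' @param corpus List of samples, each a list with elements `time`
#'   (normalized, in `[0, 1]`), `posture` (a [labeled_posture()]), and
#'   optionally `embryo` (an id used by `holdout`).
#' @param holdout Optional embryo id whose samples are excluded entirely
#'   (leave-one-embryo-out evaluation).
#' @param n_knots Number of time knots (default 11: deciles).
#' @return Object of class `posture_template`.
#' @export
fit_templates <- function(corpus, holdout = NULL, n_knots = 11L) {
  stopifnot(is.list(corpus))
  if (length(corpus) == 0L) stop("empty corpus")
  if (!is.null(holdout)) {
    ids <- vapply(corpus, function(e) as.character(e$embryo %||% NA), "")
    corpus <- corpus[is.na(match(ids, as.character(holdout)))]
  }
  if (length(corpus) == 0L) stop("empty corpus (after holdout exclusion)")
  np <- vapply(corpus, function(e) nrow(e$posture$left), integer(1))
  if (length(unique(np)) != 1L)
    stop("corpus mixes pair counts; fit pre-Q and post-Q templates separately")
  times <- vapply(corpus, function(e) as.numeric(e$time), numeric(1))
  stopifnot(all(is.finite(times)), all(times >= 0), all(times <= 1))

  feats <- do.call(rbind, lapply(seq_along(corpus), function(i) {
    ft <- posture_feature_table(corpus[[i]]$posture)
    ft$time <- times[i]
    ft
  }))

  knots <- sort(unique(stats::quantile(times, probs = seq(0, 1, length.out = n_knots),
                                       type = 1, names = FALSE)))
  feats$knot <- vapply(feats$time, function(t) knots[which.min(abs(knots - t))], numeric(1))

  fam_sd <- tapply(feats$value, feats$family, stats::sd)
  fam_sd[!is.finite(fam_sd)] <- 0
  fam_sd <- stats::setNames(as.numeric(fam_sd), names(fam_sd))
  floors <- pmax(1e-6 * fam_sd, 1e-8)

  agg <- stats::aggregate(value ~ family + position + knot, data = feats,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sd = if (length(v) >= 2) stats::sd(v) else NA_real_))
  tab <- data.frame(family = agg$family, position = agg$position, t = agg$knot,
                    n = agg$value[, "n"], mean = agg$value[, "mean"],
                    sd = agg$value[, "sd"], stringsAsFactors = FALSE)
  borrow <- !is.finite(tab$sd)
  if (any(borrow)) {
    warning(sum(borrow), " time bin(s) with < 2 samples: borrowing the ",
            "corpus-wide family sd")
    tab$sd[borrow] <- fam_sd[tab$family[borrow]]
  }
  tab$sd <- pmax(tab$sd, floors[tab$family])
  tab <- tab[order(tab$family, tab$position, tab$t), ]
  rownames(tab) <- NULL

  new_posture_template(np[1L], tab[, c("family", "position", "t", "mean", "sd")],
                       floors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_posture_template <- function(n_pairs, tab, floors) {
  index <- split(tab, paste(tab$family, tab$position, sep = "@"))
  structure(list(n_pairs = as.integer(n_pairs), table = tab,
                 floors = floors, index = index),
            class = "posture_template")
}

#' @export
print.posture_template <- function(x, ...) {
  cat("Posture template:", x$n_pairs, "pairs,",
      length(unique(x$table$family)), "feature families,",
      length(unique(x$table$t)), "time knot(s)\n")
  invisible(x)
}

#' Look up template mean and sd
#'
#' Piecewise-linear interpolation in normalized time between the fitted
#' knots; constant extrapolation beyond the first/last knot.
#'
#' @param template A [fit_templates()] result.
#' @param family Feature family name.
#' @param position Body position index (1 = tail-anchored).
#' @param t Normalized time in `[0, 1]`.
#' @return List with numeric elements `mean` and `sd`.
#' @export
template_at <- function(template, family, position, t) {
  rec <- template$index[[paste(family, position, sep = "@")]]
  if (is.null(rec))
    stop("template has no record for family '", family, "' at position ", position)
  if (nrow(rec) == 1L) return(list(mean = rec$mean, sd = rec$sd))
  list(mean = stats::approx(rec$t, rec$mean, xout = t, rule = 2)$y,
       sd = stats::approx(rec$t, rec$sd, xout = t, rule = 2)$y)
}

#' Standardized squared-z dissimilarity
#'
#' The cost contribution of one feature measurement against its template:
#' `weight * ((value - mean) / sd)^2`.  Smooth, nonnegative, and additive
#' across features, satisfying the solver's nonnegativity contract.
#'
#' @param value Observed feature value.
#' @param mean,sd Template mean and standard deviation (`sd > 0`).
#' @param weight Nonnegative family weight.
#' @return Nonnegative cost.
#' @export
standardized_cost <- function(value, mean, sd, weight = 1) {
  if (any(sd <= 0)) stop("template sd fell below its positive floor")
  if (any(weight < 0)) stop("weight must be nonnegative")
  weight * ((value - mean) / sd)^2
}

# ---- model compilation -----------------------------------------------------

#' Compile a posture model into a matching problem
#'
#' Builds the hypergraph matching problem for identifying `n_pairs`
#' bilateral pairs among `nrow(points)` candidate nuclei at a given
#' developmental time.  The branch size is `k = 2` (one bilateral pair per
#' branch) and the branch order runs posterior to anterior, starting at
#' the tail pair: `T, V6, [Q,] V5, ..., H0`.  Within a branch, the odd
#' vertex is the left nucleus and the even vertex the right.
#'
#' Tensors by degree: 2 (lateral distances and side chords), 4 and 6 (the
#' Pairs families on sequential pairs and triplets), and for the Posture
#' model one lazy maximum-degree tensor carrying the standardized
#' posture-wide feature sums, evaluable only at the final branch.  All
#' costs are standardized squared z-scores and hence nonnegative.  Extra
#' points (`n2 > n1`) simply remain unassigned.
#'
#' @param points Numeric `n2 x 3` matrix of candidate nucleus coordinates
#'   (micrometers).
#' @param n_pairs Number of bilateral pairs to identify (10 pre-Q, 11
#'   post-Q; the imaging protocol knows the stage, so this is an explicit
#'   input, never inferred from the point count).
#' @param template A [fit_templates()] result with matching `n_pairs`.
#' @param time Normalized developmental time of the frame, in `[0, 1]`.
#' @param spec A [model_spec()].
#' @return A [matching_problem()] with `k = 2` and named vertices.
#' @export
build_problem <- function(points, n_pairs, template, time,
                          spec = model_spec("posture")) {
  X <- as.matrix(points)
  stopifnot(ncol(X) == 3L, all(is.finite(X)))
  n_pairs <- as.integer(n_pairs)
  n1 <- 2L * n_pairs
  n2 <- nrow(X)
  if (n2 < n1) stop("point count n2 = ", n2, " is below n1 = ", n1)
  if (template$n_pairs != n_pairs)
    stop("template was fit for ", template$n_pairs, " pairs, not ", n_pairs)
  stopifnot(inherits(spec, "model_spec"))
  P <- n_pairs
  pair_names_tail <- rev(seam_pair_names(n_pairs))
  vertex_names <- as.vector(rbind(paste0(pair_names_tail, "L"),
                                  paste0(pair_names_tail, "R")))
  w <- spec$weights

  # template mean/sd per family, evaluated once at this frame's time
  tmpl <- function(family, positions) {
    mu <- numeric(length(positions)); sd <- numeric(length(positions))
    for (i in seq_along(positions)) {
      ms <- template_at(template, family, positions[i], time)
      mu[i] <- ms$mean; sd[i] <- ms$sd
    }
    list(mu = mu, sd = sd)
  }
  zcost <- function(value, ms, p, family) {
    w[[family]] * ((value - ms$mu[p]) / ms$sd[p])^2
  }

  tensors <- list()

  lat <- tmpl("lateral", seq_len(P))
  tensors$lateral <- dissimilarity_tensor(
    2L, cbind(2L * seq_len(P) - 1L, 2L * seq_len(P)),
    function(vt, pmat) {
      p <- (vt[1L] + 1L) %/% 2L
      d <- .row_norm(X[pmat[, 2L], , drop = FALSE] - X[pmat[, 1L], , drop = FALSE])
      zcost(d, lat, p, "lateral")
    }, mode = "precomputed", family = "lateral")

  stopifnot(P >= 2L)
  seg <- seq_len(P - 1L)
  cl <- tmpl("chord_left", seg)
  tensors$chord_left <- dissimilarity_tensor(
    2L, cbind(2L * seg - 1L, 2L * seg + 1L),
    function(vt, pmat) {
      p <- (vt[1L] + 1L) %/% 2L
      d <- .row_norm(X[pmat[, 2L], , drop = FALSE] - X[pmat[, 1L], , drop = FALSE])
      zcost(d, cl, p, "chord_left")
    }, mode = "precomputed", family = "chord_left")
  cr <- tmpl("chord_right", seg)
  tensors$chord_right <- dissimilarity_tensor(
    2L, cbind(2L * seg, 2L * seg + 2L),
    function(vt, pmat) {
      p <- vt[1L] %/% 2L
      d <- .row_norm(X[pmat[, 2L], , drop = FALSE] - X[pmat[, 1L], , drop = FALSE])
      zcost(d, cr, p, "chord_right")
    }, mode = "precomputed", family = "chord_right")

  quad_fams <- intersect(c("ratio", "mid_dist", "cos_sides",
                           "twist_phi", "twist_tau"), spec$families)
  if (length(quad_fams) > 0L && P >= 2L) {
    qt <- lapply(stats::setNames(quad_fams, quad_fams), tmpl, positions = seg)
    tensors$pairs4 <- dissimilarity_tensor(
      4L, cbind(2L * seg - 1L, 2L * seg, 2L * seg + 1L, 2L * seg + 2L),
      function(vt, pmat) {
        p <- (vt[1L] + 1L) %/% 2L
        q <- .quad_features(X[pmat[, 1L], , drop = FALSE],
                            X[pmat[, 2L], , drop = FALSE],
                            X[pmat[, 3L], , drop = FALSE],
                            X[pmat[, 4L], , drop = FALSE])
        total <- 0
        for (f in quad_fams) total <- total + zcost(q[[f]], qt[[f]], p, f)
        total
      }, mode = "precomputed", family = "pairs4")
  }

  six_fams <- intersect(c("bend_theta", "planar"), spec$families)
  if (length(six_fams) > 0L && P >= 3L) {
    tri <- seq_len(P - 2L)
    st <- lapply(stats::setNames(six_fams, six_fams), tmpl, positions = tri)
    tensors$pairs6 <- dissimilarity_tensor(
      6L, cbind(2L * tri - 1L, 2L * tri, 2L * tri + 1L, 2L * tri + 2L,
                2L * tri + 3L, 2L * tri + 4L),
      function(vt, pmat) {
        p <- (vt[1L] + 1L) %/% 2L
        s <- .six_features(X[pmat[, 1L], , drop = FALSE],
                           X[pmat[, 2L], , drop = FALSE],
                           X[pmat[, 3L], , drop = FALSE],
                           X[pmat[, 4L], , drop = FALSE],
                           X[pmat[, 5L], , drop = FALSE],
                           X[pmat[, 6L], , drop = FALSE])
        total <- 0
        for (f in six_fams) total <- total + zcost(s[[f]], st[[f]], p, f)
        total
      }, mode = "lazy", family = "pairs6")
  }

  sum_fams <- intersect(.sum_families, spec$families)
  if (length(sum_fams) > 0L) {
    su <- lapply(stats::setNames(sum_fams, sum_fams), tmpl, positions = 1L)
    tensors$posture_full <- dissimilarity_tensor(
      n1, matrix(seq_len(n1), nrow = 1L),
      function(vt, pmat) {
        n <- nrow(pmat)
        sums <- matrix(0, n, 7L,
                       dimnames = list(NULL, .sum_families))
        for (p in seq_len(P - 1L)) {
          q <- .quad_features(X[pmat[, 2L * p - 1L], , drop = FALSE],
                              X[pmat[, 2L * p], , drop = FALSE],
                              X[pmat[, 2L * p + 1L], , drop = FALSE],
                              X[pmat[, 2L * p + 2L], , drop = FALSE])
          sums[, "sum_ratio"] <- sums[, "sum_ratio"] + q$ratio
          sums[, "sum_mid_dist"] <- sums[, "sum_mid_dist"] + q$mid_dist
          sums[, "sum_cos_sides"] <- sums[, "sum_cos_sides"] + q$cos_sides
          sums[, "sum_twist_phi"] <- sums[, "sum_twist_phi"] + q$twist_phi
          sums[, "sum_twist_tau"] <- sums[, "sum_twist_tau"] + q$twist_tau
        }
        for (p in seq_len(max(P - 2L, 0L))) {
          s <- .six_features(X[pmat[, 2L * p - 1L], , drop = FALSE],
                             X[pmat[, 2L * p], , drop = FALSE],
                             X[pmat[, 2L * p + 1L], , drop = FALSE],
                             X[pmat[, 2L * p + 2L], , drop = FALSE],
                             X[pmat[, 2L * p + 3L], , drop = FALSE],
                             X[pmat[, 2L * p + 4L], , drop = FALSE])
          sums[, "sum_bend_theta"] <- sums[, "sum_bend_theta"] + s$bend_theta
          sums[, "sum_planar"] <- sums[, "sum_planar"] + s$planar
        }
        total <- 0
        for (f in sum_fams) total <- total + zcost(sums[, f], su[[f]], 1L, f)
        total
      }, mode = "lazy", family = "posture_full")
  }

  matching_problem(n1, n2, 2L, unname(tensors), vertex_names = vertex_names)
}

# ---- structured-text template files ---------------------------------------

#' Write a posture template to a structured-text file
#'
#' One record per feature-family, body-position, and time knot; values
#' printed with enough digits that a read/write round trip is lossless to
#' 12 significant digits.
#'
#' @param template A [fit_templates()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_template <- function(template, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ehgm posture template v1", con)
  writeLines(paste0("n_pairs\t", template$n_pairs), con)
  for (f in names(template$floors))
    writeLines(paste("floor", f, format(template$floors[[f]], digits = 17),
                     sep = "\t"), con)
  tab <- template$table
  writeLines(paste("knot", tab$family, tab$position,
                   format(tab$t, digits = 17),
                   format(tab$mean, digits = 17),
                   format(tab$sd, digits = 17), sep = "\t"), con)
  invisible(path)
}

#' Read a posture template written by [write_template()]
#'
#' @param path File path.
#' @return Object of class `posture_template`.
#' @export
read_template <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(parts, `[[`, "", 1L)
  n_pairs <- as.integer(parts[[which(kind == "n_pairs")[1L]]][2L])
  fl <- parts[kind == "floor"]
  floors <- stats::setNames(vapply(fl, function(p) as.numeric(p[3L]), numeric(1)),
                            vapply(fl, `[[`, "", 2L))
  kn <- parts[kind == "knot"]
  tab <- data.frame(family = vapply(kn, `[[`, "", 2L),
                    position = as.integer(vapply(kn, `[[`, "", 3L)),
                    t = as.numeric(vapply(kn, `[[`, "", 4L)),
                    mean = as.numeric(vapply(kn, `[[`, "", 5L)),
                    sd = as.numeric(vapply(kn, `[[`, "", 6L)),
                    stringsAsFactors = FALSE)
  new_posture_template(n_pairs, tab, floors)
}
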