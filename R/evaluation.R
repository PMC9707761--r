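# Evaluation metrics (top-x accuracy, cost ratio), the synthetic
# experiment runner, and point-set / corpus file I/O.

#' Top-x posture identification accuracy
#'
#' The fraction of samples whose fully correct assignment (every cell
#' identified) appears among the `x` lowest-cost solutions returned for
#' that sample.  Exact assignment equality is required; the metric is
#' nondecreasing in `x`.
#'
#' @param results List of `ehgm_result` or `solution_pool` objects, one
#'   per sample, aligned with `truths`.
#' @param truths List (or matrix rows) of ground-truth complete
#'   assignments.
#' @param x Rank cutoff (`>= 1`).
#' @return Fraction in `[0, 1]`.
#' @export
top_x_accuracy <- function(results, truths, x = 1L) {
  stopifnot(x >= 1L)
  if (is.matrix(truths)) truths <- asplit(truths, 1L)
  if (length(results) != length(truths))
    stop("results and truths must be aligned sample-by-sample")
  hit <- vapply(seq_along(results), function(i) {
    pool <- results[[i]]
    if (inherits(pool, "ehgm_result")) pool <- pool$pool
    A <- pool$assignments
    n <- min(x, nrow(A))
    truth <- as.integer(truths[[i]])
    n > 0L && any(vapply(seq_len(n), function(r) all(A[r, ] == truth), logical(1)))
  }, logical(1))
  mean(hit)
}

#' Cost ratio of the correct posture to the returned posture
#'
#' The objective value of the correct assignment divided by that of the
#' returned (cost-minimizing) assignment.  A ratio above 1 means the model
#' preferred an incorrect hypothesis to the truth; when the returned
#' assignment is the solver's proven optimum the ratio is `>= 1`, and it
#' is exactly 1 when the model ranks the truth optimal.
#'
#' @param problem The [matching_problem()] both assignments refer to.
#' @param correct The ground-truth complete assignment.
#' @param returned The solver's returned complete assignment.
#' @return Ratio (nonnegative double).
#' @export
cost_ratio <- function(problem, correct, returned) {
  num <- evaluate_objective(problem, correct)
  den <- evaluate_objective(problem, returned)
  if (den <= 0)
    stop("returned posture has zero cost; report absolute costs instead")
  num / den
}

#' Parse a seed schedule into a count of tail-anchored pairs
#'
#' Schedules are named after the most anterior seeded pair, seeding the
#' contiguous run of pairs from the tail: `"none"`, `"T"`, `"T-V6"`,
#' `"T-V5"`, ... (post-Q, `"T-V5"` spans T, V6, Q, V5).  An integer is
#' returned unchanged.
#'
#' @param schedule Schedule name or integer count.
#' @param n_pairs Number of bilateral pairs of the model.
#' @return Integer count of seeded pairs (0 for `"none"`).
#' @export
parse_seed_schedule <- function(schedule, n_pairs) {
  if (is.numeric(schedule)) return(as.integer(schedule))
  schedule <- as.character(schedule)
  if (identical(schedule, "none")) return(0L)
  names_tail <- rev(seam_pair_names(n_pairs))
  if (identical(schedule, "T")) return(1L)
  parts <- strsplit(schedule, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || parts[1L] != "T")
    stop("seed schedule must be 'none', 'T', or 'T-<pair>'")
  s <- match(parts[2L], names_tail)
  if (is.na(s)) stop("unknown pair '", parts[2L], "' in seed schedule")
  s
}

#' Configure a synthetic posture-identification experiment
#'
#' @param model Model name: `"sides"`, `"pairs"`, or `"posture"`.
#' @param seed_schedule `"none"`, `"T"`, `"T-V6"`, `"T-V5"`, ... (seeding
#'   contiguous pairs from the tail), or an integer count of tail pairs.
#' @param x Pool size (top-x reporting).
#' @param time_limit Per-sample solver wall-clock budget in seconds
#'   (default 4 hours, the conventional cap for full-size worms).
#' @param rng_seed Integer seed; the whole experiment is deterministic
#'   given this value.
#' @param sim An [embryo_sim_config()] describing the synthetic embryos.
#' @param n_corpus_embryos Simulated embryos used to fit the template.
#' @param n_test_frames Test frames to match (drawn as additional
#'   embryos).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(model = "posture", seed_schedule = "none",
                              x = 3L, time_limit = 4 * 3600,
                              rng_seed = 1L,
                              sim = reduced_worm_config(),
                              n_corpus_embryos = 6L,
                              n_test_frames = 10L) {
  structure(list(model = model, seed_schedule = seed_schedule,
                 x = as.integer(x), time_limit = time_limit,
                 rng_seed = as.integer(rng_seed), sim = sim,
                 n_corpus_embryos = as.integer(n_corpus_embryos),
                 n_test_frames = as.integer(n_test_frames)),
            class = "experiment_config")
}

#' Run a synthetic posture-identification experiment
#'
#' Simulates a corpus of labeled embryos, fits a time-dependent template,
#' simulates fresh test frames, solves each with the requested model and
#' seed schedule, and aggregates the evaluation metrics.  Deterministic
#' given `config$rng_seed`.
#'
#' Samples that hit the time limit are flagged not-proved-optimal but
#' still contribute their pool to the accuracy metrics.
#'
#' @param config An [experiment_config()].
#' @return Object of class `ehgm_report`: list with per-sample `results`
#'   (each holding the pool, truth, stats and cost ratio) and aggregate
#'   `top1`, `top2`, `top3`, `median_cost_ratio`, `median_wall_seconds`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$rng_seed)
  sim <- config$sim
  n_pairs <- sim$n_pairs
  corpus <- corpus_from_series(
    lapply(seq_len(config$n_corpus_embryos), function(i) generate_series(sim)))
  template <- fit_templates(corpus)
  spec <- model_spec(config$model)
  n_seed_pairs <- parse_seed_schedule(config$seed_schedule, n_pairs)

  # test frames drawn round-robin from fresh embryos
  test_frames <- list()
  while (length(test_frames) < config$n_test_frames) {
    s <- generate_series(sim)
    take <- min(length(s), config$n_test_frames - length(test_frames))
    test_frames <- c(test_frames, s[seq_len(take)])
  }

  results <- lapply(seq_along(test_frames), function(i) {
    fr <- test_frames[[i]]
    problem <- build_problem(fr$points, n_pairs, template, fr$time, spec)
    seeds <- rep(NA_integer_, 2L * n_pairs)
    if (n_seed_pairs > 0L) {
      sv <- seq_len(2L * n_seed_pairs)
      seeds[sv] <- fr$truth[sv]
    }
    res <- ehgm_solve(problem, seeds = seeds, x = config$x,
                      time_limit = config$time_limit)
    best <- res$pool$assignments[1L, ]
    list(sample_id = i, result = res, truth = fr$truth,
         cost_ratio = cost_ratio(problem, fr$truth, best),
         wall_seconds = res$stats$wall_seconds,
         proved_optimal = res$stats$proved_optimal)
  })

  pools <- lapply(results, `[[`, "result")
  truths <- lapply(results, `[[`, "truth")
  structure(list(
    config = config,
    results = results,
    top1 = top_x_accuracy(pools, truths, 1L),
    top2 = top_x_accuracy(pools, truths, 2L),
    top3 = top_x_accuracy(pools, truths, 3L),
    median_cost_ratio = stats::median(vapply(results, `[[`, numeric(1), "cost_ratio")),
    median_wall_seconds = stats::median(vapply(results, `[[`, numeric(1), "wall_seconds"))),
    class = "ehgm_report")
}

#' @export
print.ehgm_report <- function(x, ...) {
  cat("Posture identification experiment (", x$config$model, " model, seeds: ",
      as.character(x$config$seed_schedule), ")\n", sep = "")
  cat(sprintf("  samples: %d   top-1 %.2f  top-2 %.2f  top-3 %.2f\n",
              length(x$results), x$top1, x$top2, x$top3))
  cat(sprintf("  median cost ratio %.4f   median wall %.2fs\n",
              x$median_cost_ratio, x$median_wall_seconds))
  invisible(x)
}

# ---- point-set and corpus files -------------------------------------------

#' Read a point-set CSV
#'
#' Expects a header with columns `x_um`, `y_um`, `z_um` (additional
#' columns such as `cell_name`, `frame`, `embryo_id` are preserved as
#' attributes of the result).  Malformed coordinates are reported with
#' their row number.
#'
#' @param path CSV file path.
#' @return Numeric `n x 3` matrix of coordinates (row order preserved).
#' @export
read_pointset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "z_um")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("point-set file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  for (cn in need) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      stop("non-numeric coordinate in ", path, ", column ", cn,
           ", row ", bad[1L])
    df[[cn]] <- v
  }
  m <- as.matrix(df[, need, drop = FALSE])
  dimnames(m) <- NULL
  extra <- setdiff(names(df), need)
  if (length(extra) > 0L) attr(m, "extra") <- df[, extra, drop = FALSE]
  m
}

#' Write a point-set CSV
#'
#' Coordinates are printed with enough digits for a lossless round trip
#' to 9 significant digits; row order is preserved.
#'
#' @param points Numeric `n x 3` matrix.
#' @param path Output path.
#' @param extra Optional data.frame of additional columns (e.g.
#'   `cell_name`, `frame`, `embryo_id`).
#' @return Invisibly, `path`.
#' @export
write_pointset <- function(points, path, extra = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  df <- data.frame(x_um = format(points[, 1L], digits = 12, trim = TRUE),
                   y_um = format(points[, 2L], digits = 12, trim = TRUE),
                   z_um = format(points[, 3L], digits = 12, trim = TRUE))
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a labeled corpus CSV
#'
#' One row per nucleus with columns
#' `cell_name,x_um,y_um,z_um,frame,embryo_id`; `cell_name` is a pair name
#' suffixed `L` or `R` (e.g. `H1L`, `TR`).
#'
#' @param corpus Corpus list as accepted by [fit_templates()]; entries may
#'   carry `frame` and `embryo` ids (defaults are assigned otherwise).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labeled_corpus <- function(corpus, path) {
  rows <- list()
  for (i in seq_along(corpus)) {
    e <- corpus[[i]]
    po <- e$posture
    frame <- e$frame %||% i
    embryo <- e$embryo %||% 1L
    P <- nrow(po$left)
    rows[[i]] <- data.frame(
      cell_name = c(paste0(po$names, "L"), paste0(po$names, "R")),
      x_um = format(c(po$left[, 1L], po$right[, 1L]), digits = 12, trim = TRUE),
      y_um = format(c(po$left[, 2L], po$right[, 2L]), digits = 12, trim = TRUE),
      z_um = format(c(po$left[, 3L], po$right[, 3L]), digits = 12, trim = TRUE),
      frame = frame, embryo_id = embryo)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labeled corpus CSV written by [write_labeled_corpus()]
#'
#' Groups rows by `(embryo_id, frame)`, reconstructs each labeled posture,
#' and normalizes time per embryo as `(frame - min) / (max - min)` (0 for
#' a single-frame embryo).
#'
#' @param path CSV path with columns
#'   `cell_name,x_um,y_um,z_um,frame,embryo_id`.
#' @return Corpus list of `(time, posture, embryo, frame)` samples.
#' @export
read_labeled_corpus <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_name", "x_um", "y_um", "z_um", "frame", "embryo_id")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("corpus file lacks column(s): ", paste(missing, collapse = ", "))
  out <- list()
  for (em in unique(df$embryo_id)) {
    sub <- df[df$embryo_id == em, ]
    fr_range <- range(sub$frame)
    for (f in sort(unique(sub$frame))) {
      g <- sub[sub$frame == f, ]
      side <- substring(g$cell_name, nchar(g$cell_name))
      pair <- substring(g$cell_name, 1L, nchar(g$cell_name) - 1L)
      names_order <- seam_pair_names(length(unique(pair)))
      if (!setequal(pair, names_order))
        stop("frame ", f, " of embryo ", em,
             " does not contain one L and one R nucleus per canonical pair")
      left <- right <- matrix(NA_real_, length(names_order), 3L)
      for (p in seq_along(names_order)) {
        li <- which(pair == names_order[p] & side == "L")
        ri <- which(pair == names_order[p] & side == "R")
        if (length(li) != 1L || length(ri) != 1L)
          stop("pair ", names_order[p], " in frame ", f, " of embryo ", em,
               " must appear exactly once per side")
        left[p, ] <- as.numeric(g[li, c("x_um", "y_um", "z_um")])
        right[p, ] <- as.numeric(g[ri, c("x_um", "y_um", "z_um")])
      }
      time <- if (fr_range[2L] > fr_range[1L])
        (f - fr_range[1L]) / (fr_range[2L] - fr_range[1L]) else 0
      out[[length(out) + 1L]] <- list(time = time,
                                      posture = labeled_posture(left, right, time),
                                      embryo = em, frame = f)
    }
  }
  out
}

#' Write ranked posture hypotheses as JSON-lines-style records
#'
#' One structured-text record per hypothesis: sample id, rank, cost, then
#' `cell_name=point_index` pairs (branch order).
#'
#' @param result An `ehgm_result`.
#' @param problem The [matching_problem()] it solved (for vertex names).
#' @param sample_id Identifier written into each record.
#' @param file Connection or path ("" for stdout).
#' @return Invisibly, the lines written.
#' @export
write_ranked_postures <- function(result, problem, sample_id = 1L, file = "") {
  pool <- result$pool
  nm <- problem$vertex_names %||% as.character(seq_len(problem$n1))
  lines <- vapply(seq_along(pool$costs), function(r) {
    pairs <- paste0(nm, "=", pool$assignments[r, ], collapse = ",")
    paste(sample_id, r, format(pool$costs[r], digits = 12), pairs, sep = "\t")
  }, "")
  writeLines(lines, con = if (identical(file, "")) stdout() else file)
  invisible(lines)
}
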