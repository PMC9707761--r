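# The EHGM branch-and-bound search: greedy queue construction via the
# selection rules H1/Hm, lazy high-degree aggregation via Im, pruning
# against an incumbent pool, seeding, and exact top-x convergence.

# Vertices of branch m (branch order).
branch_vertices <- function(problem, m) {
  ((m - 1L) * problem$k + 1L):(m * problem$k)
}

# Sum the costs of the tuple group `groups[[m]]` for a batch of branch-m
# candidates.  `assigned` carries points committed at branches 1..m-1;
# `cand` holds one candidate k-tuple per row.
branch_cost_batch <- function(problem, assigned, m, cand, groups) {
  total <- numeric(nrow(cand))
  off <- (m - 1L) * problem$k
  for (e in groups[[m]]) {
    tn <- problem$tensors[[e$tensor]]
    for (r in e$rows) {
      vt <- tn$vertex_tuples[r, ]
      pmat <- matrix(0L, nrow(cand), length(vt))
      for (j in seq_along(vt)) {
        v <- vt[j]
        pmat[, j] <- if (v > off) cand[, v - off] else assigned[v]
      }
      total <- total + tensor_cost(tn, vt, pmat)
    }
  }
  total
}

# Convert a user-facing committed list of k-tuples into an assignment vector.
committed_to_assigned <- function(problem, committed) {
  assigned <- rep(NA_integer_, problem$n1)
  for (m in seq_along(committed)) {
    km <- as.integer(committed[[m]])
    if (length(km) != problem$k) stop("each committed branch must hold k points")
    assigned[branch_vertices(problem, m)] <- km
  }
  validate_assignment(assigned, problem)
}

#' Initial branch selection cost H1
#'
#' Scores a candidate permutation for the first branch: the sum of all
#' degree `1..k` tensor costs whose vertex tuples lie entirely within
#' branch 1.  This is the cost that orders the root queue.
#'
#' @param problem A [matching_problem()].
#' @param K1 Ordered k-tuple of point indices proposed for branch 1.
#' @return Nonnegative cost.
#' @export
initial_branch_cost <- function(problem, K1) {
  K1 <- as.integer(K1)
  if (length(K1) != problem$k) stop("K1 must hold k point indices")
  if (anyDuplicated(K1)) stop("K1 must hold distinct point indices")
  assigned <- rep(NA_integer_, problem$n1)
  branch_cost_batch(problem, assigned, 1L, matrix(K1, nrow = 1L),
                    problem$branch_H)
}

#' General branch selection cost Hm
#'
#' Scores a candidate permutation for branch `m >= 2`: the sum of
#' degree `1..2k` tensor costs over vertex tuples that include at least
#' one branch-`m` vertex and otherwise only vertices committed at
#' branches `1..m-1`.
#'
#' @inheritParams initial_branch_cost
#' @param committed List of the `m - 1` committed k-tuples (branch order).
#' @param Km Ordered k-tuple of point indices proposed for branch `m`.
#' @return Nonnegative cost.
#' @export
general_branch_cost <- function(problem, committed, Km) {
  m <- length(committed) + 1L
  if (m < 2L) stop("general_branch_cost applies to branches m >= 2")
  assigned <- committed_to_assigned(problem, committed)
  Km <- as.integer(Km)
  if (anyDuplicated(Km)) stop("Km must hold distinct point indices")
  if (any(Km %in% assigned[!is.na(assigned)]))
    stop("Km reuses a point already committed at an earlier branch")
  branch_cost_batch(problem, assigned, m, matrix(Km, nrow = 1L),
                    problem$branch_H)
}

#' Aggregation cost Im
#'
#' The dissimilarity attributable to higher-degree (`2k < d <= mk`) lazy
#' tensors that become evaluable once branch `m` is committed: vertex
#' tuples including at least one branch-`m` vertex and otherwise only
#' committed vertices.  Zero when no such tensors exist.
#'
#' @inheritParams general_branch_cost
#' @return Nonnegative cost.
#' @export
aggregation_cost <- function(problem, committed, Km) {
  m <- length(committed) + 1L
  assigned <- committed_to_assigned(problem, committed)
  Km <- as.integer(Km)
  if (any(Km %in% assigned[!is.na(assigned)]))
    stop("Km reuses a point already committed at an earlier branch")
  branch_cost_batch(problem, assigned, m, matrix(Km, nrow = 1L),
                    problem$branch_I)
}

# Enumerate feasible branch-m candidate k-tuples given committed points and
# seeds.  Seeded vertices admit only their seeded point; points seeded to
# vertices of later branches are withheld from free slots.
feasible_candidates <- function(problem, assigned, m, seeds) {
  vs <- branch_vertices(problem, m)
  used <- assigned[!is.na(assigned)]
  future <- seq_len(problem$n1) > max(vs)
  reserved <- seeds[future & !is.na(seeds)]
  avail <- setdiff(seq_len(problem$n2), c(used, reserved))
  choices <- lapply(vs, function(v) {
    if (!is.na(seeds[v])) setdiff(seeds[v], used) else avail
  })
  cand <- as.matrix(expand.grid(rev(choices), KEEP.OUT.ATTRS = FALSE))
  cand <- cand[, rev(seq_len(ncol(cand))), drop = FALSE]  # slot 1 varies slowest
  dimnames(cand) <- NULL
  storage.mode(cand) <- "integer"
  if (problem$k > 1L && nrow(cand) > 0L) {
    ok <- !apply(cand, 1L, anyDuplicated)
    cand <- cand[ok, , drop = FALSE]
  }
  cand
}

#' Build the ordered queue for a branch
#'
#' Enumerates every feasible k-permutation of unused points for branch `m`
#' (seeded vertices admit only their seeded point), scores each with the
#' selection rule (`H1` at the root, `Hm` below), and returns them sorted
#' ascending with lexicographic tie-breaks.  An empty queue signals that
#' the subtree is infeasible under the seeds (a backtrack, not an error).
#'
#' @inheritParams general_branch_cost
#' @param seeds Optional seed assignment: integer vector of length `n1`
#'   with `NA` for free vertices (see [as_seed_vector()]), or `NULL`.
#' @return List of class `branch_queue` with elements `m`, `points`
#'   (candidate matrix, one k-tuple per row) and `H` (ascending costs).
#' @export
build_queue <- function(problem, committed, m = length(committed) + 1L,
                        seeds = NULL) {
  assigned <- committed_to_assigned(problem, committed)
  seeds <- as_seed_vector(seeds, problem)
  cand <- feasible_candidates(problem, assigned, m, seeds)
  if (nrow(cand) == 0L) {
    return(structure(list(m = m, points = cand, H = numeric(0)),
                     class = "branch_queue"))
  }
  H <- branch_cost_batch(problem, assigned, m, cand, problem$branch_H)
  ord <- order_by_cost_lex(H, cand)
  structure(list(m = m, points = cand[ord, , drop = FALSE], H = H[ord]),
            class = "branch_queue")
}

#' @export
print.branch_queue <- function(x, ...) {
  cat("Branch", x$m, "queue:", length(x$H), "entries\n")
  n <- min(length(x$H), 10L)
  for (i in seq_len(n))
    cat(sprintf("  H = %.6g  (%s)\n", x$H[i], paste(x$points[i, ], collapse = " ")))
  if (length(x$H) > n) cat("  ...\n")
  invisible(x)
}

#' Normalize seed input
#'
#' Accepts `NULL` (no seeds), a full-length integer vector with `NA` for
#' free vertices, or a named integer vector whose names are vertex names
#' (when the problem carries them) or vertex indices.
#'
#' @param seeds Seed specification.
#' @param problem A [matching_problem()].
#' @return Integer vector of length `n1` with `NA` for free vertices.
#' @export
as_seed_vector <- function(seeds, problem) {
  n1 <- problem$n1
  if (is.null(seeds)) return(rep(NA_integer_, n1))
  if (!is.null(names(seeds)) && any(names(seeds) != "")) {
    out <- rep(NA_integer_, n1)
    nm <- names(seeds)
    idx <- if (!is.null(problem$vertex_names)) match(nm, problem$vertex_names)
           else suppressWarnings(as.integer(nm))
    if (anyNA(idx)) stop("unknown vertex name(s) in seeds: ",
                         paste(nm[is.na(idx)], collapse = ", "))
    out[idx] <- as.integer(seeds)
    seeds <- out
  }
  validate_assignment(seeds, problem)
}

#' Exact hypergraph matching by branch-and-bound
#'
#' Depth-first search over branch permutations: each branch's queue is
#' ordered by the greedy selection rule (`H1`/`Hm`), lazy high-degree
#' tensors are aggregated (`Im`) upon committing a branch, and subtrees
#' whose accumulated cost exceeds the incumbent bound are pruned.  Because
#' every cost increment is nonnegative, the accumulated partial cost is a
#' valid lower bound and the search is exact: with no time limit, the
#' returned pool is exactly the `x` lowest-cost complete assignments
#' consistent with the seeds (ties lexicographic).
#'
#' Pruning is against the pool's x-th best cost, so a single search proves
#' the full top-`x` set.  An entry equal in cost to the x-th best is
#' admitted only if lexicographically smaller, making pools deterministic.
#'
#' In the returned stats, `nodes_expanded` counts every queue entry popped
#' and examined (including entries discarded by the bound check right
#' after popping) and `prunes` counts entries eliminated by the bound.
#'
#' @inheritParams build_queue
#' @param x Pool size: the search returns (and proves) the top-`x` set.
#' @param time_limit Optional wall-clock budget in seconds (default
#'   `Inf`).  Checked cooperatively between node expansions; on expiry the
#'   pool holds the best solutions found and `proved_optimal` is `FALSE`.
#' @param warm_start Optional complete assignment whose cost initializes
#'   the incumbent bound (it is inserted into the pool).
#' @return List of class `ehgm_result` with elements `pool` (a
#'   `solution_pool`) and `stats` (`nodes_expanded`, `prunes`,
#'   `completions`, `proved_optimal`, `wall_seconds`).
#' @export
ehgm_solve <- function(problem, seeds = NULL, x = 1L, time_limit = Inf,
                       warm_start = NULL) {
  stopifnot(inherits(problem, "matching_problem"), x >= 1L)
  x <- as.integer(x)
  seeds <- as_seed_vector(seeds, problem)
  n1 <- problem$n1; k <- problem$k; M <- problem$M
  t0 <- proc.time()[["elapsed"]]
  deadline <- if (is.finite(time_limit)) t0 + time_limit else Inf

  st <- new.env(parent = emptyenv())
  st$costs <- numeric(0)
  st$A <- matrix(NA_integer_, 0L, n1)
  st$nodes <- 0L; st$prunes <- 0L; st$completions <- 0L
  st$timed_out <- FALSE

  bound <- function() if (nrow(st$A) < x) Inf else st$costs[x]

  pool_insert <- function(a, cost) {
    if (nrow(st$A) >= x) {
      worst <- st$costs[x]
      if (cost > worst) return(invisible())
      if (cost == worst && !lex_less(a, st$A[x, ])) return(invisible())
    }
    A2 <- rbind(st$A, a)
    c2 <- c(st$costs, cost)
    ord <- order_by_cost_lex(c2, A2)
    keep <- ord[seq_len(min(x, length(ord)))]
    st$A <- A2[keep, , drop = FALSE]
    st$costs <- c2[keep]
    invisible()
  }

  if (!is.null(warm_start)) {
    w <- validate_assignment(warm_start, problem, complete = TRUE)
    if (any(!is.na(seeds) & seeds != w))
      stop("warm_start conflicts with seeds")
    pool_insert(w, evaluate_objective(problem, w))
  }

  descend <- function(m, assigned, acc) {
    if (st$timed_out) return(invisible())
    cand <- feasible_candidates(problem, assigned, m, seeds)
    nq <- nrow(cand)
    if (nq == 0L) return(invisible())
    H <- branch_cost_batch(problem, assigned, m, cand, problem$branch_H)
    ord <- order_by_cost_lex(H, cand)
    cand <- cand[ord, , drop = FALSE]; H <- H[ord]
    has_I <- length(problem$branch_I[[m]]) > 0L
    vs <- branch_vertices(problem, m)
    for (i in seq_len(nq)) {
      if (proc.time()[["elapsed"]] > deadline) {
        st$timed_out <- TRUE
        return(invisible())
      }
      st$nodes <- st$nodes + 1L
      if (acc + H[i] > bound()) {
        # queue is ascending in H, so every remaining entry is bounded out
        st$prunes <- st$prunes + (nq - i + 1L)
        return(invisible())
      }
      inc <- H[i]
      if (has_I) {
        inc <- inc + branch_cost_batch(problem, assigned, m,
                                       cand[i, , drop = FALSE],
                                       problem$branch_I)
        if (acc + inc > bound()) {
          st$prunes <- st$prunes + 1L
          next
        }
      }
      a2 <- assigned
      a2[vs] <- cand[i, ]
      if (m == M) {
        st$completions <- st$completions + 1L
        pool_insert(a2, acc + inc)
      } else {
        descend(m + 1L, a2, acc + inc)
        if (st$timed_out) return(invisible())
      }
    }
    invisible()
  }

  descend(1L, rep(NA_integer_, n1), 0)
  wall <- proc.time()[["elapsed"]] - t0
  pool <- new_solution_pool(x, st$A, st$costs)
  structure(list(pool = pool,
                 stats = list(nodes_expanded = st$nodes,
                              prunes = st$prunes,
                              completions = st$completions,
                              proved_optimal = !st$timed_out,
                              wall_seconds = wall)),
            class = "ehgm_result")
}

#' @export
print.ehgm_result <- function(x, ...) {
  s <- x$stats
  cat("EHGM search:",
      if (s$proved_optimal) "proved optimal" else "time limit reached", "\n")
  cat(sprintf("  nodes examined %d, pruned %d, completions %d, wall %.2fs\n",
              s$nodes_expanded, s$prunes, s$completions, s$wall_seconds))
  print(x$pool)
  invisible(x)
}

#' Serialize search stats as a flat structured-text record
#'
#' @param result An `ehgm_result`.
#' @param file Connection or path ("" for stdout).
#' @return Invisibly, the lines written.
#' @export
write_search_stats <- function(result, file = "") {
  s <- result$stats
  lines <- c(paste0("nodes_expanded\t", s$nodes_expanded),
             paste0("prunes\t", s$prunes),
             paste0("completions\t", s$completions),
             paste0("proved_optimal\t", tolower(as.character(s$proved_optimal))),
             paste0("wall_seconds\t", format(s$wall_seconds, digits = 6)))
  writeLines(lines, con = if (identical(file, "")) stdout() else file)
  invisible(lines)
}

#' Per-branch decomposition of the objective
#'
#' Splits the full objective of a complete assignment into its per-branch
#' selection (`Hm`) and aggregation (`Im`) contributions.  The partition
#' fully accounts for the objective: `sum(H + I)` equals
#' [evaluate_objective()] up to floating-point roundoff (asserted at 1e-9
#' relative tolerance in the test suite).
#'
#' @inheritParams evaluate_objective
#' @return Data frame with columns `m`, `H`, `I`.
#' @export
decompose_objective <- function(problem, assignment) {
  a <- validate_assignment(assignment, problem, complete = TRUE)
  M <- problem$M
  H <- numeric(M); I <- numeric(M)
  assigned <- rep(NA_integer_, problem$n1)
  for (m in seq_len(M)) {
    vs <- branch_vertices(problem, m)
    km <- matrix(a[vs], nrow = 1L)
    H[m] <- branch_cost_batch(problem, assigned, m, km, problem$branch_H)
    I[m] <- branch_cost_batch(problem, assigned, m, km, problem$branch_I)
    assigned[vs] <- a[vs]
  }
  data.frame(m = seq_len(M), H = H, I = I)
}
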