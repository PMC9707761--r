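# Core domain types for hypergraph matching: assignments, dissimilarity
# tensors, matching problems, solution pools, and the exhaustive oracle.

#' Number of branch steps of a search
#'
#' A hypergraph with `n1` model vertices solved with branch size `k` is
#' explored in `M = n1 / k` branch steps; branch `m` assigns vertices
#' `(m-1)k + 1, ..., mk` (in branch order).
#'
#' @param n1 Model vertex count (positive integer).
#' @param k Branch size: number of vertices assigned per branch step.
#' @return The integer branch count `M`.
#' @examples
#' count_branch_steps(20, 2) # 10
#' count_branch_steps(22, 2) # 11
#' @export
count_branch_steps <- function(n1, k) {
  stopifnot(is.numeric(n1), is.numeric(k), n1 >= 1, k >= 1)
  if (n1 %% k != 0) stop("branch size must divide vertex count")
  as.integer(n1 %/% k)
}

#' Number of candidate permutations at a branch
#'
#' Each branch step selects an ordered `k`-tuple of distinct point indices
#' from the `n2` observed points, so a queue over all points holds the
#' falling factorial `n2 * (n2 - 1) * ... * (n2 - k + 1)` entries.
#'
#' @param n2 Observed point count.
#' @param k Branch size.
#' @return The number of ordered `k`-tuples (falling factorial), as a double.
#' @examples
#' branch_permutation_count(4, 2) # 12
#' @export
branch_permutation_count <- function(n2, k) {
  stopifnot(is.numeric(n2), is.numeric(k), k >= 1)
  if (k > n2) stop("branch size k cannot exceed the point count n2")
  prod(seq(n2, n2 - k + 1))
}

#' Construct a dissimilarity tensor
#'
#' A degree-`d` dissimilarity tensor assigns a finite, nonnegative cost to
#' each correspondence between an in-scope vertex `d`-tuple and an ordered
#' point `d`-tuple.  Nonnegativity is a hard contract: the solver prunes
#' against accumulated partial cost, which is a valid lower bound only when
#' every increment is `>= 0`.  Models with negative raw costs must be
#' shifted by the caller.
#'
#' Vertex tuples are canonical: strictly increasing in branch order.  Point
#' tuples carry the corresponding order and contain distinct indices.
#'
#' @param degree Hyperedge degree `d` (number of vertices spanned).
#' @param vertex_tuples Integer matrix with `degree` columns; each row a
#'   strictly increasing vertex tuple in scope.
#' @param cost Function `(vt, pmat)` where `vt` is one vertex tuple (row of
#'   `vertex_tuples`) and `pmat` an integer matrix of point tuples (one per
#'   row); must return one finite nonnegative cost per row, vectorized.
#' @param mode `"precomputed"` for degrees `<= 2k` (evaluated before/while
#'   ordering queues) or `"lazy"` for higher degrees (evaluated only at
#'   time of branching).
#' @param family Optional label describing what the tensor measures.
#' @return An object of class `dissimilarity_tensor`.
#' @export
dissimilarity_tensor <- function(degree, vertex_tuples, cost,
                                 mode = c("precomputed", "lazy"),
                                 family = NULL) {
  mode <- match.arg(mode)
  degree <- as.integer(degree)
  vertex_tuples <- matrix(as.integer(vertex_tuples), ncol = degree)
  if (nrow(vertex_tuples) == 0L) stop("tensor scope is empty")
  if (degree > 1L) {
    inc <- apply(vertex_tuples, 1L, function(v) all(diff(v) > 0))
    if (!all(inc)) stop("vertex tuples must be strictly increasing in branch order")
  }
  stopifnot(is.function(cost))
  structure(list(degree = degree, vertex_tuples = vertex_tuples,
                 cost = cost, mode = mode, family = family),
            class = "dissimilarity_tensor")
}

# Evaluate one tensor on a batch of point tuples, enforcing the
# finite-nonnegative contract at the single choke point.
tensor_cost <- function(tensor, vt, pmat) {
  v <- as.vector(tensor$cost(vt, pmat))
  if (length(v) != nrow(pmat))
    stop("tensor cost function returned ", length(v), " values for ",
         nrow(pmat), " point tuples")
  if (any(!is.finite(v)) || any(v < 0))
    stop("dissimilarity costs must be finite and nonnegative (contract violation)")
  v
}

#' Construct a table-backed dissimilarity tensor
#'
#' Stores an explicit cost array per in-scope vertex tuple, indexed by the
#' point tuple.  A lookup outside the stored scope is an error (never an
#' implicit zero), which catches model-construction bugs.  Mostly useful
#' for random test instances and tiny worked examples.
#'
#' @inheritParams dissimilarity_tensor
#' @param values List with one numeric array of dimension `rep(n2, degree)`
#'   per row of `vertex_tuples` (or a single array recycled for all rows).
#' @param n2 Observed point count the arrays are indexed over.
#' @return An object of class `dissimilarity_tensor`.
#' @export
table_tensor <- function(degree, vertex_tuples, values, n2,
                         mode = c("precomputed", "lazy"), family = NULL) {
  degree <- as.integer(degree)
  vertex_tuples <- matrix(as.integer(vertex_tuples), ncol = degree)
  if (!is.list(values)) values <- list(values)
  if (length(values) == 1L) values <- rep(values, nrow(vertex_tuples))
  if (length(values) != nrow(vertex_tuples))
    stop("need one cost array per vertex tuple")
  for (a in values) {
    if (length(a) != as.integer(n2)^degree)
      stop("cost array has wrong size for n2 = ", n2, ", degree = ", degree)
    if (any(!is.finite(a)) || any(a < 0))
      stop("table tensor entries must be finite and nonnegative")
  }
  keys <- apply(vertex_tuples, 1L, paste, collapse = ",")
  names(values) <- keys
  n2 <- as.integer(n2)
  cost <- function(vt, pmat) {
    key <- paste(vt, collapse = ",")
    a <- values[[key]]
    if (is.null(a)) stop("undefined hyperedge cost")
    # linear index into the degree-d array
    idx <- pmat[, 1L]
    if (degree > 1L) {
      mult <- 1
      for (j in 2:degree) {
        mult <- mult * n2
        idx <- idx + (pmat[, j] - 1L) * mult
      }
    }
    a[idx]
  }
  dissimilarity_tensor(degree, vertex_tuples, cost, mode, family)
}

#' Construct a hypergraph matching problem
#'
#' Bundles the problem dimensions, the branch size, and the dissimilarity
#' tensors that define the matching objective.  Vertices `1..n1` are in
#' branch order: branch `m` assigns vertices `(m-1)k + 1, ..., mk`.
#' Tensors of degree `<= 2k` must be `"precomputed"` and higher degrees
#' `"lazy"`, mirroring which terms are available to the selection rule
#' versus the aggregation rule.
#'
#' @param n1 Model vertex count.
#' @param n2 Observed point count (`n2 >= n1`; extra points simply remain
#'   unassigned).
#' @param k Branch size; must divide `n1`.
#' @param tensors List of [dissimilarity_tensor()] objects.
#' @param vertex_names Optional character vector of length `n1` naming the
#'   vertices in branch order.
#' @return An object of class `matching_problem`.
#' @export
matching_problem <- function(n1, n2, k, tensors, vertex_names = NULL) {
  n1 <- as.integer(n1); n2 <- as.integer(n2); k <- as.integer(k)
  if (n1 > n2) stop("n1 must not exceed n2")
  M <- count_branch_steps(n1, k)
  stopifnot(is.list(tensors), length(tensors) > 0)
  for (tn in tensors) {
    if (!inherits(tn, "dissimilarity_tensor")) stop("tensors must be dissimilarity_tensor objects")
    if (tn$degree > n1) stop("tensor degree exceeds n1")
    if (any(tn$vertex_tuples < 1L | tn$vertex_tuples > n1))
      stop("vertex tuple indices out of range")
    want <- if (tn$degree <= 2L * k) "precomputed" else "lazy"
    if (tn$mode != want)
      stop("tensor of degree ", tn$degree, " must be mode '", want,
           "' for branch size k = ", k)
  }
  if (!is.null(vertex_names)) stopifnot(length(vertex_names) == n1)
  # Index tuples by the branch at which they become evaluable: the branch
  # of a tuple's largest vertex.  Split into selection-rule (H, degree
  # <= 2k) and aggregation-rule (I, degree > 2k) groups.
  branch_H <- vector("list", M)
  branch_I <- vector("list", M)
  for (i in seq_along(tensors)) {
    tn <- tensors[[i]]
    b <- as.integer(ceiling(apply(tn$vertex_tuples, 1L, max) / k))
    for (m in unique(b)) {
      rows <- which(b == m)
      entry <- list(tensor = i, rows = rows)
      if (tn$degree <= 2L * k) branch_H[[m]] <- c(branch_H[[m]], list(entry))
      else branch_I[[m]] <- c(branch_I[[m]], list(entry))
    }
  }
  structure(list(n1 = n1, n2 = n2, k = k, M = M, tensors = tensors,
                 vertex_names = vertex_names,
                 branch_H = branch_H, branch_I = branch_I),
            class = "matching_problem")
}

#' @export
print.matching_problem <- function(x, ...) {
  degs <- sort(unique(vapply(x$tensors, `[[`, integer(1), "degree")))
  cat("Hypergraph matching problem\n")
  cat("  vertices (n1):", x$n1, " points (n2):", x$n2,
      " branch size k:", x$k, " branches M:", x$M, "\n")
  cat("  tensor degrees:", paste(degs, collapse = ", "), "\n")
  invisible(x)
}

# ---- assignments -----------------------------------------------------------

# Assignments are integer vectors of length n1 (branch order); NA marks an
# unassigned vertex.  Injectivity over non-NA entries is required.
validate_assignment <- function(assignment, problem, complete = FALSE) {
  a <- as.integer(assignment)
  if (length(a) != problem$n1)
    stop("assignment must have length n1 = ", problem$n1)
  got <- a[!is.na(a)]
  if (any(got < 1L | got > problem$n2)) stop("point index out of range")
  if (anyDuplicated(got)) stop("assignment is not injective: a point index repeats")
  if (complete && anyNA(a)) stop("assignment is incomplete")
  a
}

# strict lexicographic comparison of two complete mappings
lex_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0L)
  length(i) > 0L && d[i[1L]] < 0L
}

# order rows of A by cost, ties lexicographic on the mapping
order_by_cost_lex <- function(costs, A) {
  do.call(order, c(list(costs), lapply(seq_len(ncol(A)), function(j) A[, j])))
}

#' Evaluate the full hypergraph matching objective
#'
#' Sums, over every tensor and every in-scope vertex tuple, the cost of the
#' point tuple induced by a complete assignment.  This is the objective the
#' solver minimizes; it is deterministic for fixed inputs.
#'
#' @param problem A [matching_problem()].
#' @param assignment Complete assignment: integer vector of length `n1`
#'   giving the point index of each vertex (branch order).
#' @return The total cost (nonnegative double).
#' @export
evaluate_objective <- function(problem, assignment) {
  a <- validate_assignment(assignment, problem, complete = TRUE)
  total <- 0
  for (tn in problem$tensors) {
    vts <- tn$vertex_tuples
    for (r in seq_len(nrow(vts))) {
      vt <- vts[r, ]
      total <- total + tensor_cost(tn, vt, matrix(a[vt], nrow = 1L))
    }
  }
  total
}

# Vectorized objective over many assignments (rows of A).  Used by the
# brute-force oracle.
evaluate_objective_many <- function(problem, A) {
  costs <- numeric(nrow(A))
  for (tn in problem$tensors) {
    vts <- tn$vertex_tuples
    for (r in seq_len(nrow(vts))) {
      vt <- vts[r, ]
      costs <- costs + tensor_cost(tn, vt, A[, vt, drop = FALSE])
    }
  }
  costs
}

#' Enumerate every injective completion of a partial assignment
#'
#' Materializes all complete assignments consistent with the given seeds,
#' one per row, in lexicographic order of the mapping.  The count is the
#' falling factorial `(n2 - s)! / (n2 - n1)!` where `s` seeds are fixed.
#' Intended for oracle use on small instances; guarded at 1e6 rows.
#'
#' @inheritParams evaluate_objective
#' @param seeds Optional partial assignment (length-`n1` integer vector
#'   with `NA` for free vertices), or `NULL`.
#' @return Integer matrix, one complete assignment per row.
#' @export
enumerate_assignments <- function(problem, seeds = NULL) {
  n1 <- problem$n1; n2 <- problem$n2
  s <- if (is.null(seeds)) rep(NA_integer_, n1) else validate_assignment(seeds, problem)
  free <- sum(is.na(s))
  count <- prod(seq(n2 - (n1 - free), by = -1, length.out = free))
  if (count > 1e6)
    stop("enumeration would produce ", format(count), " assignments; ",
         "use ehgm_solve() for instances this large")
  A <- matrix(integer(0), nrow = 1L, ncol = 0L)
  for (v in seq_len(n1)) {
    r <- nrow(A)
    if (!is.na(s[v])) {
      if (ncol(A) > 0L && any(A == s[v])) {
        keep <- rowSums(A == s[v]) == 0L
        A <- A[keep, , drop = FALSE]
        r <- nrow(A)
        if (r == 0L) stop("seeds conflict: duplicate point index")
      }
      A <- cbind(A, rep(s[v], r))
    } else {
      cand <- rep(seq_len(n2), times = r)
      big <- A[rep(seq_len(r), each = n2), , drop = FALSE]
      # exclude points used earlier in the row or reserved by later seeds
      used <- if (ncol(A) > 0L) rowSums(big == cand) > 0L else rep(FALSE, length(cand))
      later_seeds <- s[seq_len(n1) > v & !is.na(s)]
      reserved <- cand %in% later_seeds
      keep <- !(used | reserved)
      A <- cbind(big[keep, , drop = FALSE], cand[keep])
    }
  }
  colnames(A) <- NULL
  A[do.call(order, lapply(seq_len(ncol(A)), function(j) A[, j])), , drop = FALSE]
}

# ---- solution pool ---------------------------------------------------------

new_solution_pool <- function(capacity, assignments, costs) {
  assignments <- as.matrix(assignments)
  dimnames(assignments) <- NULL
  structure(list(capacity = capacity,
                 assignments = assignments,
                 costs = as.vector(costs)),
            class = "solution_pool")
}

#' @export
print.solution_pool <- function(x, ...) {
  cat("Solution pool (capacity ", x$capacity, "): ",
      length(x$costs), " entr", if (length(x$costs) == 1) "y" else "ies", "\n", sep = "")
  for (i in seq_along(x$costs)) {
    cat(sprintf("  #%d cost %.6g: %s\n", i, x$costs[i],
                paste(x$assignments[i, ], collapse = " ")))
  }
  invisible(x)
}

#' @export
length.solution_pool <- function(x) length(x$costs)

#' Exhaustive ground-truth solver
#'
#' Enumerates every injective completion of `seeds`, evaluates the full
#' objective on each, and returns the `x` lowest-cost complete assignments
#' (ties broken by lexicographic order of the mapping).  This is the
#' oracle the branch-and-bound solver is verified against; it is only
#' feasible on small instances.
#'
#' @inheritParams enumerate_assignments
#' @param x Pool size: how many lowest-cost assignments to keep.
#' @return A `solution_pool` with at most `x` entries sorted ascending.
#' @export
brute_force_solve <- function(problem, seeds = NULL, x = 1L) {
  stopifnot(x >= 1L)
  A <- enumerate_assignments(problem, seeds)
  costs <- evaluate_objective_many(problem, A)
  ord <- order_by_cost_lex(costs, A)
  keep <- ord[seq_len(min(x, length(ord)))]
  new_solution_pool(x, A[keep, , drop = FALSE], costs[keep])
}

#' Generate a random matching problem
#'
#' Builds a table-backed problem with dense scope (every strictly
#' increasing vertex tuple of each requested degree) and i.i.d. uniform
#' `[0, 1]` costs, using R's current RNG stream.  Used for solver
#' verification against the exhaustive oracle.
#'
#' @inheritParams matching_problem
#' @param degrees Integer vector of hyperedge degrees to include.
#' @return A [matching_problem()].
#' @export
random_matching_problem <- function(n1, n2, k, degrees = c(1L, 2L)) {
  tensors <- lapply(degrees, function(d) {
    vts <- t(utils::combn(n1, d))
    vals <- lapply(seq_len(nrow(vts)), function(i) {
      array(stats::runif(n2^d), dim = rep(n2, d))
    })
    table_tensor(d, vts, vals, n2,
                 mode = if (d <= 2L * k) "precomputed" else "lazy")
  })
  matching_problem(n1, n2, k, tensors)
}

#' Dump a problem's tensor scope as structured text
#'
#' Writes one line per (degree, vertex tuple, point tuple, cost) for every
#' in-scope vertex tuple at a given complete assignment.  Debugging aid.
#'
#' @inheritParams evaluate_objective
#' @param file Connection or file path ("" for stdout).
#' @return Invisibly, the lines written.
#' @export
dump_problem <- function(problem, assignment, file = "") {
  a <- validate_assignment(assignment, problem, complete = TRUE)
  lines <- character(0)
  for (tn in problem$tensors) {
    for (r in seq_len(nrow(tn$vertex_tuples))) {
      vt <- tn$vertex_tuples[r, ]
      cost <- tensor_cost(tn, vt, matrix(a[vt], nrow = 1L))
      lines <- c(lines, paste(tn$degree,
                              paste(vt, collapse = ","),
                              paste(a[vt], collapse = ","),
                              format(cost, digits = 12), sep = "\t"))
    }
  }
  writeLines(lines, con = if (identical(file, "")) stdout() else file)
  invisible(lines)
}
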