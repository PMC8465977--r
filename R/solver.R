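#' @useDynLib probdom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# session-local counter used to mint unique solver-cache tokens
.probdom_env <- new.env(parent = emptyenv())
.probdom_env$instance_counter <- 0L

new_cache_token <- function() {
  .probdom_env$instance_counter <- .probdom_env$instance_counter + 1L
  sprintf("inst%d", .probdom_env$instance_counter)
}

# Build the index-space instance handed to the C++ engine: 1-based adjacency
# lists plus log-space coefficients min(-log(failure), log_cap), and the
# threshold T = -log(1 - theta). Computed once per (network, query) and
# reused across re-solves.
solver_instance <- function(net, q) {
  stopifnot(inherits(net, "weighted_network"))
  nodes <- net$nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  adj <- rep(list(integer()), n)
  cf <- rep(list(numeric()), n)
  if (nrow(net$edges) > 0) {
    ui <- idx[net$edges$u]
    vi <- idx[net$edges$v]
    co <- pmin(-log(net$edges$failure), q$log_cap)
    co[net$edges$failure >= 1] <- 0 # weight 0: contributes nothing
    ends <- c(ui, vi)
    other <- c(vi, ui)
    coefs <- c(co, co)
    o <- order(ends, other)
    ends <- ends[o]; other <- other[o]; coefs <- coefs[o]
    sp <- split(seq_along(ends), ends)
    for (key in names(sp)) {
      i <- as.integer(key)
      adj[[i]] <- other[sp[[key]]]
      cf[[i]] <- coefs[sp[[key]]]
    }
  }
  list(n = n, nodes = nodes, idx = idx, adj = adj, coef = cf,
       T = -log(1 - q$theta), eps = q$epsilon)
}

new_pmds_solution <- function(members, optimal = TRUE) {
  structure(list(members = sort(members),
                 size = length(members),
                 objective_optimal = optimal),
            class = "pmds_solution")
}

#' @export
print.pmds_solution <- function(x, ...) {
  cat(sprintf("pmds_solution: %d driver node(s)%s\n", x$size,
              if (x$objective_optimal) " (proven optimal)" else ""))
  if (x$size <= 20) cat(" ", paste(x$members, sep = "", collapse = ", "), "\n")
  invisible(x)
}

# target >= 0 switches the engine to decision mode: the exact size is only
# needed up to the question "does the optimum exceed `target`?". A result
# with size target + 1 and objective_optimal = FALSE then means "proven
# greater than target" (infeasibility under the fixings is folded into the
# same answer); exact sizes are returned whenever the optimum is <= target.
solve_instance <- function(inst, forced_in_idx, forced_out_idx, max_nodes,
                           cache_token = "", target = -1L) {
  forced <- integer(inst$n)
  forced[forced_in_idx] <- 1L
  forced[forced_out_idx] <- -1L
  res <- tryCatch(
    pd_solve_cpp(inst$n, inst$adj, inst$coef, inst$T, inst$eps, forced,
                 max_nodes, cache_token, as.integer(target)),
    error = function(e) {
      stop(errorCondition(
        sprintf("exact solver failed: %s", conditionMessage(e)),
        class = c("probdom_solver_failure", "error")))
    })
  if (identical(res$status, "infeasible")) {
    stop(errorCondition(
      "no feasible driver set exists under the given fixings",
      class = c("probdom_infeasible", "error")))
  }
  if (isTRUE(res$proved_gt_target)) {
    return(structure(list(members = NULL, size = target + 1L,
                          objective_optimal = FALSE),
                     class = "pmds_solution"))
  }
  new_pmds_solution(inst$nodes[res$members])
}

#' Solve the probabilistic minimum dominating set problem exactly
#'
#' Finds a minimum-cardinality driver set S such that every node either
#' belongs to S or is covered by its neighbours in S with probability at
#' least `theta`: in log space, for every node `v` with `deg(v) > 0`,
#' `T * x_v + sum over edges (u,v) of c_uv * x_u >= T` where
#' `c_uv = min(-log(failure_uv), log_cap)` and `T = -log(1 - theta)`;
#' degree-0 nodes are always selected. Optimality is proven by exhaustive
#' branch-and-bound search; a suboptimal answer is never returned silently.
#'
#' @param net a [weighted_network()].
#' @param q a [coverage_query()].
#' @param forced_in,forced_out character vectors of nodes fixed inside /
#'   outside the driver set (must be disjoint).
#' @param max_nodes search-node budget before the solver aborts with an
#'   error of class `probdom_solver_failure`.
#' @return a `pmds_solution` with elements `members`, `size` and
#'   `objective_optimal`. If the fixings admit no feasible driver set, an
#'   error of class `probdom_infeasible` is signalled (distinct from solver
#'   failure).
#' @examples
#' net <- weighted_network(data.frame(u = "a", v = "b", weight = 0.8))
#' solve_pmds(net, coverage_query(0.5))$size
#' @export
solve_pmds <- function(net, q, forced_in = character(),
                       forced_out = character(), max_nodes = 5e7) {
  stopifnot(inherits(net, "weighted_network"), inherits(q, "coverage_query"))
  if (length(intersect(forced_in, forced_out)) > 0) {
    stop("`forced_in` and `forced_out` must be disjoint")
  }
  unknown <- setdiff(c(forced_in, forced_out), net$nodes)
  if (length(unknown) > 0) {
    stop(sprintf("unknown node '%s' in fixings", unknown[1]))
  }
  inst <- solver_instance(net, q)
  solve_instance(inst, inst$idx[forced_in], inst$idx[forced_out], max_nodes)
}

#' Solve the classical minimum dominating set problem exactly
#'
#' Classical (non-probabilistic) domination: every node is in S or adjacent
#' to a node in S. Solved by the same exact engine with every edge treated
#' as a certain interaction.
#'
#' @param net a [weighted_network()].
#' @param max_nodes search-node budget.
#' @return a `pmds_solution`.
#' @export
solve_mds <- function(net, max_nodes = 5e7) {
  stopifnot(inherits(net, "weighted_network"))
  q <- coverage_query(0.5) # placeholder; coefficients overridden below
  inst <- solver_instance(net, q)
  inst$T <- 1
  inst$eps <- 1e-9
  inst$coef <- lapply(inst$adj, function(a) rep(2, length(a)))
  solve_instance(inst, integer(), integer(), max_nodes)
}

#' Enumerate all minimum feasible driver sets by brute force
#'
#' Exhaustive subset enumeration in increasing size order, used as the
#' independent oracle for the exact solver and the control-role classifier
#' on small instances. Feasibility uses the same capped log-space threshold
#' as the solver.
#'
#' @param net a [weighted_network()] with at most `guard` nodes.
#' @param q a [coverage_query()].
#' @param guard refuse instances larger than this (default 20; enumeration
#'   is exponential).
#' @return a list of character vectors, each a minimum feasible driver set.
#' @export
brute_force_minimum_sets <- function(net, q, guard = 20L) {
  stopifnot(inherits(net, "weighted_network"), inherits(q, "coverage_query"))
  n <- length(net$nodes)
  if (n > guard) {
    stop(sprintf("brute force refused: %d nodes exceeds guard of %d",
                 n, guard))
  }
  inst <- solver_instance(net, q)
  C <- matrix(0, n, n)
  if (nrow(net$edges) > 0) {
    ui <- inst$idx[net$edges$u]
    vi <- inst$idx[net$edges$v]
    co <- pmin(-log(net$edges$failure), q$log_cap)
    co[net$edges$failure >= 1] <- 0
    C[cbind(ui, vi)] <- co
    C[cbind(vi, ui)] <- co
  }
  thr <- inst$T - inst$eps
  for (k in 0:n) {
    found <- list()
    if (k == 0L) {
      subsets <- matrix(integer(), nrow = 0, ncol = 1)
    } else {
      subsets <- utils::combn(n, k)
    }
    n_sub <- if (k == 0L) 1L else ncol(subsets)
    for (j in seq_len(n_sub)) {
      s <- if (k == 0L) integer() else subsets[, j]
      cov <- if (length(s) == 0L) numeric(n) else
        colSums(C[s, , drop = FALSE])
      in_s <- logical(n)
      in_s[s] <- TRUE
      if (all(in_s | cov >= thr)) {
        found[[length(found) + 1L]] <- net$nodes[s]
      }
    }
    if (length(found) > 0) return(found)
  }
  stop("internal error: full node set should always be feasible")
}
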