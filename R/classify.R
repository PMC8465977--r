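# Control-role classification: every node is critical (in all minimum
# feasible driver sets), intermittent (in some but not all) or redundant
# (in none). Three sound reduction rules classify many nodes from the graph
# structure alone; the remainder is settled by exact re-solves with the node
# in question forced in or out of the driver set.

# adjacency with weights, as a list keyed by node
adjacency_table <- function(net) {
  adj <- rep(list(data.frame(nbr = character(), weight = numeric())),
             length(net$nodes))
  names(adj) <- net$nodes
  e <- net$edges
  if (nrow(e) > 0) {
    ends <- c(e$u, e$v)
    other <- c(e$v, e$u)
    w <- c(e$weight, e$weight)
    sp <- split(seq_along(ends), ends)
    for (key in names(sp)) {
      adj[[key]] <- data.frame(nbr = other[sp[[key]]], weight = w[sp[[key]]],
                               stringsAsFactors = FALSE)
    }
  }
  adj
}

#' Reduction rules for control-role preprocessing
#'
#' Three sound graph-reduction rules identify control roles without any
#' exact search:
#'
#' * `rule_critical_leaves()`: a node with two or more degree-1 neighbours,
#'   each reachable with probability above `theta`, is critical — a
#'   minimum driver set omitting it would have to select both leaves, and
#'   swapping them for the hub gives a strictly smaller feasible set.
#' * `rule_redundant_covered()`: a node of degree at least 1 whose
#'   neighbours are all critical and whose full neighbourhood covers it
#'   above `theta` is redundant — it is always covered and can only help
#'   nodes that are themselves selected.
#' * `rule_critical_uncoverable()`: a node whose entire neighbourhood
#'   cannot reach coverage `theta` (including degree-0 nodes, whose empty
#'   neighbourhood gives coverage 0) must self-select in every feasible
#'   set, hence is critical.
#'
#' Inequalities are strict with an `epsilon` guard; a rule that declines to
#' fire on a boundary tie is merely conservative, the exact stage settles
#' such nodes.
#'
#' @param net a [weighted_network()].
#' @param q a [coverage_query()].
#' @param unclassified character vector of nodes still unclassified.
#' @param known_critical nodes already established as critical by sound
#'   rules.
#' @return character vector of newly classified nodes.
#' @name reduction_rules
NULL

#' @rdname reduction_rules
#' @export
rule_critical_leaves <- function(net, q, unclassified = net$nodes) {
  adj <- adjacency_table(net)
  deg <- network_degrees(net)
  out <- character()
  for (v in intersect(net$nodes, unclassified)) {
    a <- adj[[v]]
    if (nrow(a) < 2) next
    leaves <- a[deg[a$nbr] == 1L & a$weight - q$theta > q$epsilon, ,
                drop = FALSE]
    if (nrow(leaves) >= 2) out <- c(out, v)
  }
  sort(out)
}

#' @rdname reduction_rules
#' @export
rule_redundant_covered <- function(net, q, known_critical,
                                   unclassified = net$nodes) {
  adj <- adjacency_table(net)
  out <- character()
  for (v in setdiff(intersect(net$nodes, unclassified), known_critical)) {
    a <- adj[[v]]
    if (nrow(a) == 0) next
    if (!all(a$nbr %in% known_critical)) next
    cov <- 1 - prod(1 - a$weight)
    if (cov - q$theta > q$epsilon) out <- c(out, v)
  }
  sort(out)
}

#' @rdname reduction_rules
#' @export
rule_critical_uncoverable <- function(net, q, unclassified = net$nodes) {
  adj <- adjacency_table(net)
  out <- character()
  for (v in intersect(net$nodes, unclassified)) {
    a <- adj[[v]]
    cov <- if (nrow(a) == 0) 0 else 1 - prod(1 - a$weight)
    if (q$theta - cov > q$epsilon) out <- c(out, v)
  }
  sort(out)
}

#' Preprocess a network with the reduction rules
#'
#' Applies the three [reduction rules][reduction_rules] in order (critical
#' leaves, covered redundants, uncoverable criticals) and, unless
#' `single_pass = TRUE`, repeats the sweep until no new node is classified.
#' Each rule is a sound implication, so iterating can only classify more
#' nodes correctly. The number of criticals found is a lower bound on the
#' minimum driver-set size.
#'
#' @param net a [weighted_network()].
#' @param q a [coverage_query()].
#' @param single_pass apply each rule exactly once, in order, instead of
#'   sweeping to a fixpoint.
#' @return a list with `critical`, `redundant`, `lower_bound` and `by_rule`
#'   (a named character vector mapping each preclassified node to the rule
#'   that fired: `"leaves"`, `"covered"` or `"uncoverable"`).
#' @export
preprocess_controls <- function(net, q, single_pass = FALSE) {
  stopifnot(inherits(net, "weighted_network"), inherits(q, "coverage_query"))
  critical <- character()
  redundant <- character()
  by_rule <- character()
  repeat {
    unclassified <- setdiff(net$nodes, c(critical, redundant))
    n_before <- length(critical) + length(redundant)
    new1 <- rule_critical_leaves(net, q, unclassified)
    critical <- union(critical, new1)
    by_rule[new1] <- "leaves"
    unclassified <- setdiff(unclassified, new1)
    new2 <- rule_redundant_covered(net, q, critical, unclassified)
    redundant <- union(redundant, new2)
    by_rule[new2] <- "covered"
    unclassified <- setdiff(unclassified, new2)
    new3 <- rule_critical_uncoverable(net, q, unclassified)
    critical <- union(critical, new3)
    by_rule[new3] <- "uncoverable"
    n_after <- length(critical) + length(redundant)
    if (single_pass || n_after == n_before) break
  }
  list(critical = sort(critical), redundant = sort(redundant),
       lower_bound = length(critical), by_rule = by_rule)
}

#' Classify every node's control role across all minimum driver sets
#'
#' Partitions the node set into critical (in every minimum feasible driver
#' set), intermittent (in some but not all) and redundant (in none) roles:
#'
#' 1. preprocess with the [reduction rules][reduction_rules] (optional);
#' 2. solve one exact minimum driver set S0 with preclassified criticals
#'    forced in and preclassified redundants forced out;
#' 3. for each unpreclassified member of S0, re-solve with that node forced
#'    out: a size increase or infeasibility proves it critical, otherwise
#'    it is intermittent;
#' 4. for each unpreclassified non-member, re-solve with it forced in: a
#'    size increase proves it redundant, otherwise it is intermittent.
#'
#' The result does not depend on which optimal S0 the solver returns, nor
#' on the input order of nodes.
#'
#' @param net a [weighted_network()].
#' @param q a [coverage_query()].
#' @param preprocess apply the reduction rules first (default `TRUE`); with
#'   `FALSE` every node is settled by exact re-solves. Both paths give
#'   identical partitions.
#' @param single_pass passed to [preprocess_controls()].
#' @param max_nodes per-solve search budget, see [solve_pmds()].
#' @return an object of class `control_classification`: `critical`,
#'   `intermittent`, `redundant` (character vectors partitioning the node
#'   set), `pmds_size`, `preprocessing_lower_bound`, `preprocessed_critical`,
#'   `preprocessed_redundant`, `by_rule`, `theta`, `epsilon`.
#' @examples
#' net <- weighted_network(data.frame(u = c("a", "b"), v = c("b", "c")))
#' classify_controls(net, coverage_query(0.5))
#' @export
classify_controls <- function(net, q, preprocess = TRUE, single_pass = FALSE,
                              max_nodes = 5e7) {
  stopifnot(inherits(net, "weighted_network"), inherits(q, "coverage_query"))
  if (preprocess) {
    pre <- preprocess_controls(net, q, single_pass = single_pass)
  } else {
    pre <- list(critical = character(), redundant = character(),
                lower_bound = 0L, by_rule = character())
  }
  inst <- solver_instance(net, q)
  # re-solves differ by one fixing; solved residual components are shared
  token <- new_cache_token()
  on.exit(pd_cache_clear_cpp(), add = TRUE)
  fin <- inst$idx[pre$critical]
  fout <- inst$idx[pre$redundant]
  s0 <- solve_instance(inst, fin, fout, max_nodes, token)

  critical <- pre$critical
  redundant <- pre$redundant
  intermittent <- character()

  for (v in setdiff(s0$members, pre$critical)) {
    res <- tryCatch(
      solve_instance(inst, fin, c(fout, inst$idx[v]), max_nodes, token,
                     target = s0$size),
      probdom_infeasible = function(e) NULL)
    if (is.null(res) || res$size > s0$size) {
      critical <- c(critical, v)
    } else {
      intermittent <- c(intermittent, v)
    }
  }
  for (v in setdiff(net$nodes, c(s0$members, pre$critical, pre$redundant))) {
    res <- solve_instance(inst, c(fin, inst$idx[v]), fout, max_nodes, token,
                          target = s0$size)
    if (res$size > s0$size) {
      redundant <- c(redundant, v)
    } else {
      intermittent <- c(intermittent, v)
    }
  }

  structure(list(
    critical = sort(critical),
    intermittent = sort(intermittent),
    redundant = sort(redundant),
    pmds_size = s0$size,
    preprocessing_lower_bound = pre$lower_bound,
    preprocessed_critical = pre$critical,
    preprocessed_redundant = pre$redundant,
    by_rule = pre$by_rule,
    theta = q$theta,
    epsilon = q$epsilon
  ), class = "control_classification")
}

#' @export
print.control_classification <- function(x, ...) {
  n <- length(x$critical) + length(x$intermittent) + length(x$redundant)
  cat(sprintf(
    "control_classification (theta = %g): %d nodes, driver-set size %d\n",
    x$theta, n, x$pmds_size))
  cat(sprintf("  critical: %d  intermittent: %d  redundant: %d\n",
              length(x$critical), length(x$intermittent),
              length(x$redundant)))
  cat(sprintf("  preclassified by rules: %d critical, %d redundant (lower bound %d)\n",
              length(x$preprocessed_critical),
              length(x$preprocessed_redundant),
              x$preprocessing_lower_bound))
  invisible(x)
}

#' @export
as.data.frame.control_classification <- function(x, ...) {
  nodes <- c(x$critical, x$intermittent, x$redundant)
  category <- c(rep("critical", length(x$critical)),
                rep("intermittent", length(x$intermittent)),
                rep("redundant", length(x$redundant)))
  pre <- rep("solver", length(nodes))
  known <- names(x$by_rule)
  pre[nodes %in% known] <- unname(x$by_rule[nodes[nodes %in% known]])
  out <- data.frame(node = nodes, category = category, preclassified = pre,
                    stringsAsFactors = FALSE)
  out[order(out$node), , drop = FALSE]
}

#' Write a classification table
#'
#' TSV with columns `node`, `category` (critical / intermittent /
#' redundant) and `preclassified` (which reduction rule fired, or
#' `"solver"`), sorted by node.
#'
#' @param cls a `control_classification`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(cls, path) {
  stopifnot(inherits(cls, "control_classification"))
  df <- as.data.frame(cls)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise a classification as a list (for JSON serialisation)
#' @param cls a `control_classification`.
#' @return a named list of scalar summaries.
#' @export
classification_summary <- function(cls) {
  stopifnot(inherits(cls, "control_classification"))
  list(theta = cls$theta,
       epsilon = cls$epsilon,
       pmds_size = cls$pmds_size,
       lower_bound = cls$preprocessing_lower_bound,
       n_critical = length(cls$critical),
       n_intermittent = length(cls$intermittent),
       n_redundant = length(cls$redundant),
       n_preclassified = length(cls$preprocessed_critical) +
         length(cls$preprocessed_redundant))
}
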