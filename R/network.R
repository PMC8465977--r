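#' Weighted probabilistic networks
#'
#' A `weighted_network` is a simple undirected graph whose edges carry an
#' interaction probability `weight` in `[0, 1]`. The complementary failure
#' probability `failure = 1 - weight` drives the probabilistic domination
#' semantics: a node outside a driver set S is covered when the probability
#' that at least one of its edges towards S succeeds exceeds a threshold.
#'
#' Node identifiers are opaque strings. The object canonicalises its inputs
#' (nodes sorted, each edge stored with its lexicographically smaller
#' endpoint first) so that all downstream computations are independent of
#' input order.
#'
#' @param edges a data.frame with columns `u`, `v` and optionally `weight`
#'   (defaulting to 1, a deterministic interaction). Self-loops and
#'   duplicate pairs (in either orientation) are rejected.
#' @param nodes optional character vector of node identifiers; isolated
#'   nodes (degree 0) can only be declared here. Endpoints appearing in
#'   `edges` are always included.
#' @return an object of class `weighted_network` with elements `nodes`
#'   (sorted character vector), `edges` (data.frame `u`, `v`, `weight`,
#'   `failure`) and `graph` (the underlying igraph object).
#' @examples
#' net <- weighted_network(data.frame(u = "a", v = "b", weight = 0.8))
#' network_size(net)
#' @export
weighted_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(u = character(), v = character(),
                        weight = numeric())
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) == 2L) {
    names(edges) <- c("u", "v")
    edges$weight <- 1.0
  } else if (ncol(edges) >= 3L) {
    edges <- edges[, 1:3]
    names(edges) <- c("u", "v", "weight")
  } else if (nrow(edges) > 0L) {
    stop("`edges` must have columns u, v and optionally weight")
  } else {
    edges <- data.frame(u = character(), v = character(), weight = numeric())
  }
  edges$u <- as.character(edges$u)
  edges$v <- as.character(edges$v)
  edges$weight <- as.numeric(edges$weight)

  if (anyNA(edges$u) || anyNA(edges$v) || any(!nzchar(edges$u)) ||
      any(!nzchar(edges$v))) {
    stop("edge endpoints must be non-missing, non-empty strings")
  }
  if (anyNA(edges$weight)) stop("edge weights must not be missing")
  bad_w <- edges$weight < 0 | edges$weight > 1
  if (any(bad_w)) {
    stop(sprintf("edge weight outside [0, 1]: %s-%s has weight %g",
                 edges$u[which(bad_w)[1]], edges$v[which(bad_w)[1]],
                 edges$weight[which(bad_w)[1]]))
  }
  loops <- edges$u == edges$v
  if (any(loops)) {
    stop(sprintf("self-loop on node '%s' is not allowed",
                 edges$u[which(loops)[1]]))
  }
  # canonical orientation: smaller endpoint first
  flip <- edges$u > edges$v
  tmp <- edges$u[flip]
  edges$u[flip] <- edges$v[flip]
  edges$v[flip] <- tmp
  key <- paste(edges$u, edges$v, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("duplicate edge: %s",
                 gsub("\r", "-", dup, fixed = TRUE)))
  }
  if (any(edges$weight == 0)) {
    warning(sprintf(
      "%d edge(s) have weight 0 and contribute nothing to coverage",
      sum(edges$weight == 0)))
  }
  all_nodes <- sort(unique(c(as.character(nodes), edges$u, edges$v)))
  if (length(all_nodes) == 0L) stop("network must contain at least one node")
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  edges$failure <- 1 - edges$weight

  g <- igraph::graph_from_data_frame(
    edges[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = all_nodes))
  igraph::E(g)$weight <- edges$weight

  structure(list(nodes = all_nodes, edges = edges, graph = g),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    cat(sprintf("  weights in [%.3g, %.3g]\n",
                min(x$edges$weight), max(x$edges$weight)))
  }
  invisible(x)
}

#' Number of nodes and edges
#' @param net a `weighted_network`
#' @return `network_size` returns a named integer vector with elements
#'   `nodes` and `edges`.
#' @export
network_size <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  c(nodes = length(net$nodes), edges = nrow(net$edges))
}

#' @rdname network_size
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  net$nodes
}

#' @rdname network_size
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  net$edges
}

#' Node degrees
#' @param net a `weighted_network`
#' @return named integer vector of degrees, one entry per node.
#' @export
network_degrees <- function(net) {
  d <- igraph::degree(net$graph)
  d[net$nodes]
}

#' Coverage threshold query
#'
#' Bundles the coverage threshold `theta` with the numerical knobs used by
#' the feasibility test and the exact solver: `epsilon` is an absolute
#' tolerance for inequality comparisons and `log_cap` caps the coefficient
#' `-log(failure)` when an edge is certain (`failure = 0`), keeping solver
#' coefficients finite while preserving the semantics that a single certain
#' edge always covers its endpoint.
#'
#' @param theta coverage threshold, strictly between 0 and 1: a node outside
#'   the driver set must be reached with probability at least `theta`.
#' @param epsilon absolute comparison tolerance (default `1e-9`).
#' @param log_cap cap for `-log(failure)` coefficients (default 50, i.e.
#'   a certain edge behaves as success probability `1 - exp(-50)`). Must
#'   exceed `-log(1 - theta)` so a capped edge still satisfies coverage.
#' @return an object of class `coverage_query`.
#' @export
coverage_query <- function(theta, epsilon = 1e-9, log_cap = 50) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta <= 0 || theta >= 1) {
    stop("`theta` must be a single number strictly between 0 and 1")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("`epsilon` must be a positive number")
  }
  if (!is.numeric(log_cap) || length(log_cap) != 1L ||
      log_cap <= -log(1 - theta)) {
    stop("`log_cap` must exceed -log(1 - theta)")
  }
  structure(list(theta = theta, epsilon = epsilon, log_cap = log_cap),
            class = "coverage_query")
}

#' @export
print.coverage_query <- function(x, ...) {
  cat(sprintf("coverage_query: theta = %g (epsilon = %g, log_cap = %g)\n",
              x$theta, x$epsilon, x$log_cap))
  invisible(x)
}

#' Probability that a node is covered by a driver set
#'
#' The coverage of node `v` by a set `S` combines the independent failure
#' probabilities of the edges from `v` into `S`:
#' `1 - prod(failure(u, v))` over `u` in the intersection of `S` with the
#' neighbourhood of `v`. The empty intersection gives coverage 0.
#'
#' @param v a node identifier.
#' @param S character vector of driver nodes.
#' @param net a `weighted_network`.
#' @return coverage probability in `[0, 1]`.
#' @export
coverage_probability <- function(v, S, net) {
  stopifnot(inherits(net, "weighted_network"))
  if (!v %in% net$nodes) stop(sprintf("unknown node '%s'", v))
  unknown <- setdiff(S, net$nodes)
  if (length(unknown) > 0) {
    stop(sprintf("unknown node '%s' in S", unknown[1]))
  }
  nb <- igraph::neighbors(net$graph, v)$name
  cov_nb <- intersect(nb, S)
  if (length(cov_nb) == 0L) return(0)
  eid <- igraph::get_edge_ids(net$graph, rbind(rep(v, length(cov_nb)), cov_nb))
  rho <- 1 - igraph::E(net$graph)$weight[eid]
  1 - prod(rho)
}

#' Probabilistic domination feasibility
#'
#' A driver set `S` is feasible when every node either belongs to `S` or is
#' covered by its neighbours in `S` with probability at least
#' `theta - epsilon` (the non-strict threshold form used by the exact
#' solver).
#'
#' @param S character vector of driver nodes (subset of the node set).
#' @param net a `weighted_network`.
#' @param q a [coverage_query()].
#' @return logical scalar.
#' @export
is_feasible <- function(S, net, q) {
  stopifnot(inherits(net, "weighted_network"), inherits(q, "coverage_query"))
  unknown <- setdiff(S, net$nodes)
  if (length(unknown) > 0) {
    stop(sprintf("unknown node '%s' in S", unknown[1]))
  }
  outside <- setdiff(net$nodes, S)
  for (v in outside) {
    if (coverage_probability(v, S, net) < q$theta - q$epsilon) return(FALSE)
  }
  TRUE
}

#' Read a weighted edge list
#'
#' Reads a TSV edge list with two columns (`u`, `v`; weights default to 1)
#' or three columns (`u`, `v`, `weight` in `[0, 1]`). Lines starting with
#' `#` and blank lines are ignored. Duplicate pairs and self-loops are
#' rejected; malformed lines are reported with their line number.
#'
#' @param path path to the file.
#' @return a [weighted_network()].
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path)
  # "# node:<TAB>id" comment lines declare isolated nodes (see write_edge_list)
  iso <- sub("^# node:\t", "", raw[grepl("^# node:\t", raw)])
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  if (length(lines) == 0L && length(iso) == 0L) {
    stop("edge list contains no data lines")
  }
  if (length(lines) == 0L) {
    return(weighted_network(nodes = iso))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- nf < 2L | nf > 3L
  if (any(bad)) {
    stop(sprintf("line %d: expected 2 or 3 tab-separated fields, found %d",
                 lineno[which(bad)[1]], nf[which(bad)[1]]))
  }
  u <- vapply(parts, `[[`, character(1), 1L)
  v <- vapply(parts, `[[`, character(1), 2L)
  w <- rep(1.0, length(parts))
  has_w <- nf == 3L
  if (any(has_w)) {
    wtxt <- vapply(parts[has_w], `[[`, character(1), 3L)
    wnum <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(wnum)) {
      i <- which(has_w)[which(is.na(wnum))[1]]
      stop(sprintf("line %d: weight '%s' is not a number",
                   lineno[i], wtxt[which(is.na(wnum))[1]]))
    }
    w[has_w] <- wnum
  }
  weighted_network(data.frame(u = u, v = v, weight = w,
                              stringsAsFactors = FALSE),
                   nodes = iso)
}

#' Write a weighted edge list
#'
#' Emits edges as TSV (`u`, `v`, `weight`) in lexicographic order with the
#' smaller endpoint first, so that identical networks always produce
#' byte-identical files. Isolated nodes are recorded as `# node:` comment
#' lines so a round-trip preserves the node set.
#'
#' @param net a `weighted_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  iso <- setdiff(net$nodes, unique(c(net$edges$u, net$edges$v)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# u\tv\tweight", con)
  for (v in iso) writeLines(sprintf("# node:\t%s", v), con)
  if (nrow(net$edges) > 0) {
    writeLines(sprintf("%s\t%s\t%.12g",
                       net$edges$u, net$edges$v, net$edges$weight), con)
  }
  invisible(path)
}
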