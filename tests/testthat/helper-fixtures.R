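# Small graphs and oracles shared across the test files. All fixtures are
# built in code; none are read from disk.

path3 <- function(w = 1.0) {
  weighted_network(data.frame(u = c("a", "b"), v = c("b", "c"), weight = w))
}

cycle4 <- function(w = 1.0) {
  weighted_network(data.frame(u = c("a", "b", "c", "a"),
                              v = c("b", "c", "d", "d"), weight = w))
}

star_net <- function(n_leaves = 3, w = 0.9) {
  weighted_network(data.frame(u = "hub",
                              v = sprintf("leaf%d", seq_len(n_leaves)),
                              weight = w))
}

single_edge <- function(w) {
  weighted_network(data.frame(u = "a", v = "b", weight = w))
}

# Erdos-Renyi weighted network on n nodes (uses the current RNG stream)
random_er_network <- function(n, p, unit_weights = FALSE) {
  am <- matrix(stats::runif(n * n) < p, n, n)
  am[lower.tri(am, diag = TRUE)] <- FALSE
  idx <- which(am, arr.ind = TRUE)
  nodes <- sprintf("n%02d", seq_len(n))
  edges <- if (nrow(idx) > 0) {
    data.frame(u = nodes[idx[, 1]], v = nodes[idx[, 2]],
               weight = if (unit_weights) 1.0 else stats::runif(nrow(idx)),
               stringsAsFactors = FALSE)
  } else NULL
  weighted_network(edges, nodes = nodes)
}

# classification derived purely from exhaustive enumeration
oracle_classify <- function(net, q) {
  sets <- brute_force_minimum_sets(net, q)
  in_all <- Reduce(intersect, sets)
  in_some <- Reduce(union, sets)
  list(critical = sort(in_all),
       intermittent = sort(setdiff(in_some, in_all)),
       redundant = sort(setdiff(net$nodes, in_some)),
       size = length(sets[[1]]))
}

# two-sided Fisher p by direct hypergeometric enumeration (independent of
# stats::fisher.test)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  lo <- max(0, k - n2)
  hi <- min(k, m)
  pr <- stats::dhyper(lo:hi, m, n2, k)
  pobs <- stats::dhyper(a, m, n2, k)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

expect_same_partition <- function(a, b) {
  expect_identical(a$critical, b$critical)
  expect_identical(a$intermittent, b$intermittent)
  expect_identical(a$redundant, b$redundant)
}
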