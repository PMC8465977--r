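# Weighted scale-free benchmark networks: power-law degree sequence,
# Havel-Hakimi realization, degree-preserving double edge swaps, uniform
# edge weights interpreted as interaction probabilities.

# evaluate code with a private, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the scale-free network generator
#'
#' @param n node count (at least 2).
#' @param gamma degree exponent of the power law `P(k) ~ k^-gamma`,
#'   must exceed 1.
#' @param k_avg target average degree; the sampled sequence must realise it
#'   within 10 percent relative error.
#' @param seed integer RNG seed; every stage of the generator is
#'   deterministic given the seed.
#' @param n_swaps attempted double edge swaps for randomization; default
#'   (`NULL`) is 10 times the edge count.
#' @param k_min,k_max degree support bounds; `k_max` defaults to
#'   `floor(sqrt(n))` and is tuned downwards so the expected mean degree
#'   matches `k_avg`.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n, gamma, k_avg, seed, n_swaps = NULL,
                             k_min = 1L, k_max = NULL) {
  if (!is.numeric(n) || n < 2) stop("`n` must be at least 2")
  if (!is.numeric(gamma) || gamma <= 1) stop("`gamma` must exceed 1")
  if (!is.numeric(k_avg) || k_avg <= 0) stop("`k_avg` must be positive")
  if (is.null(k_max)) k_max <- max(k_min, floor(sqrt(n)))
  if (k_min < 1 || k_min > k_max || k_max > n - 1) {
    stop("need 1 <= k_min <= k_max <= n - 1")
  }
  if (!is.null(n_swaps) && n_swaps < 0) stop("`n_swaps` must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      abs(seed) >= 2^31 - 16) {
    stop("`seed` must be a single integer below 2^31")
  }
  structure(list(n = as.integer(n), gamma = gamma, k_avg = k_avg,
                 seed = as.integer(seed),
                 n_swaps = if (is.null(n_swaps)) NULL else as.integer(n_swaps),
                 k_min = as.integer(k_min), k_max = as.integer(k_max)),
            class = "generator_config")
}

# expected mean degree of the truncated power law on [k_min, k_hi]
powerlaw_mean <- function(gamma, k_min, k_hi) {
  k <- k_min:k_hi
  sum(k^(1 - gamma)) / sum(k^(-gamma))
}

#' Sample a graphical power-law degree sequence
#'
#' Draws `n` degrees from the discrete power law `P(k) ~ k^-gamma` on
#' `[k_min, k_eff]`, where `k_eff <= k_max` is tuned so the expected mean
#' degree is as close as possible to `k_avg`. Sequences are redrawn until
#' the degree sum is even, the sequence is graphical (Erdos-Gallai, via
#' igraph) and the realised mean degree is within 10 percent of `k_avg`;
#' a bounded number of attempts guards unattainable configurations.
#'
#' @param cfg a [generator_config()].
#' @param max_attempts redraw budget (default 500).
#' @return integer vector of `n` degrees.
#' @export
sample_degree_sequence <- function(cfg, max_attempts = 500L) {
  stopifnot(inherits(cfg, "generator_config"))
  cand <- cfg$k_min:cfg$k_max
  means <- vapply(cand, function(kh) powerlaw_mean(cfg$gamma, cfg$k_min, kh),
                  numeric(1))
  k_eff <- cand[which.min(abs(means - cfg$k_avg))]
  support <- cfg$k_min:k_eff
  prob <- support^(-cfg$gamma)
  with_seed(cfg$seed, {
    for (attempt in seq_len(max_attempts)) {
      deg <- sample(support, cfg$n, replace = TRUE, prob = prob)
      if (length(support) == 1L) deg <- rep(support, cfg$n)
      if (sum(deg) %% 2 != 0) next
      if (abs(mean(deg) - cfg$k_avg) / cfg$k_avg > 0.1) next
      if (!igraph::is_graphical(deg)) next
      return(deg)
    }
    stop(sprintf(paste0(
      "no acceptable degree sequence after %d attempts: gamma = %g with ",
      "k in [%d, %d] cannot realise mean degree %g within 10%%"),
      max_attempts, cfg$gamma, cfg$k_min, k_eff, cfg$k_avg))
  })
}

#' Realize a degree sequence as a simple graph (Havel-Hakimi)
#'
#' Havel-Hakimi construction: repeatedly connect the highest-degree
#' unsaturated node to the next-highest ones (igraph's largest-first
#' realization). Edges carry unit weight.
#'
#' @param degrees integer degree sequence; must be graphical.
#' @return a [weighted_network()] with nodes `v1 ... vn` and unit weights.
#' @export
realize_degree_sequence <- function(degrees) {
  degrees <- as.integer(degrees)
  if (!igraph::is_graphical(degrees)) {
    stop("degree sequence is not graphical")
  }
  n <- length(degrees)
  node_names <- sprintf("v%d", seq_len(n))
  if (sum(degrees) == 0L) {
    return(weighted_network(nodes = node_names))
  }
  g <- igraph::realize_degseq(degrees, method = "largest")
  el <- igraph::as_edgelist(g, names = FALSE)
  weighted_network(
    data.frame(u = node_names[el[, 1]], v = node_names[el[, 2]],
               weight = 1.0, stringsAsFactors = FALSE),
    nodes = node_names)
}

#' Randomize a network by degree-preserving double edge swaps
#'
#' Performs `n_swaps` attempted double edge swaps: two distinct edges
#' `(a,b)` and `(c,d)` (each orientation randomised) are rewired to
#' `(a,d)` and `(c,b)`; the swap is rejected when it would create a
#' self-loop or a duplicate edge. The degree multiset is preserved exactly
#' and each edge keeps its weight as it moves. Deterministic given `seed`.
#'
#' @param net a [weighted_network()].
#' @param n_swaps number of attempted swaps.
#' @param seed integer RNG seed.
#' @return a rewired [weighted_network()].
#' @export
rewire_edges <- function(net, n_swaps, seed) {
  stopifnot(inherits(net, "weighted_network"))
  if (n_swaps == 0L || nrow(net$edges) < 2L) return(net)
  eu <- net$edges$u
  ev <- net$edges$v
  ew <- net$edges$weight
  m <- length(eu)
  present <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) if (a < b) paste(a, b, sep = "\r") else
    paste(b, a, sep = "\r")
  for (i in seq_len(m)) assign(ekey(eu[i], ev[i]), TRUE, envir = present)
  with_seed(seed, {
    for (t in seq_len(n_swaps)) {
      ij <- sample.int(m, 2L)
      i <- ij[1]; j <- ij[2]
      a <- eu[i]; b <- ev[i]
      if (stats::runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
      c_ <- eu[j]; d <- ev[j]
      if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      # rewire (a,b),(c,d) -> (a,d),(c,b)
      if (a == d || c_ == b) next
      k1 <- ekey(a, d); k2 <- ekey(c_, b)
      if (exists(k1, envir = present, inherits = FALSE) ||
          exists(k2, envir = present, inherits = FALSE) || k1 == k2) next
      rm(list = c(ekey(a, b), ekey(c_, d)), envir = present)
      assign(k1, TRUE, envir = present)
      assign(k2, TRUE, envir = present)
      eu[i] <- a; ev[i] <- d
      eu[j] <- c_; ev[j] <- b
    }
  })
  weighted_network(data.frame(u = eu, v = ev, weight = ew,
                              stringsAsFactors = FALSE),
                   nodes = net$nodes)
}

#' Generate a weighted scale-free benchmark network
#'
#' Pipeline: sample a graphical power-law degree sequence, realize it with
#' Havel-Hakimi, randomize with degree-preserving double edge swaps, then
#' assign every edge an independent uniform `[0, 1]` value interpreted as
#' the interaction probability `weight` (so `failure = 1 - weight`).
#' Byte-identical output for identical configurations.
#'
#' @param cfg a [generator_config()].
#' @return a list with `network` (a [weighted_network()]), `degrees` (the
#'   sampled sequence) and `provenance` (configuration echo plus realised
#'   mean degree), of class `generated_network`.
#' @examples
#' gen <- generate_scale_free_weighted(generator_config(
#'   n = 50, gamma = 2.1, k_avg = 2, seed = 1))
#' network_size(gen$network)
#' @export
generate_scale_free_weighted <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  degrees <- sample_degree_sequence(cfg)
  net <- realize_degree_sequence(degrees)
  n_swaps <- if (is.null(cfg$n_swaps)) 10L * nrow(net$edges) else cfg$n_swaps
  net <- rewire_edges(net, n_swaps, seed = cfg$seed + 1L)
  w <- with_seed(cfg$seed + 2L, stats::runif(nrow(net$edges)))
  edges <- net$edges[, c("u", "v")]
  edges$weight <- w
  out <- weighted_network(edges, nodes = net$nodes)
  structure(list(
    network = out,
    degrees = degrees,
    provenance = list(n = cfg$n, gamma = cfg$gamma, k_avg = cfg$k_avg,
                      seed = cfg$seed, n_swaps = n_swaps,
                      k_min = cfg$k_min, k_max = cfg$k_max,
                      realized_mean_degree = mean(degrees))
  ), class = "generated_network")
}

#' @export
print.generated_network <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "generated_network: n = %d, gamma = %g, <k> target %g realised %.3f (seed %d)\n",
    p$n, p$gamma, p$k_avg, p$realized_mean_degree, p$seed))
  print(x$network)
  invisible(x)
}
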