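# Age-specific dynamic weighted networks from microarray detection calls.
#
# Input is the categorical output of a presence/absence detection algorithm
# (e.g. MAS5-style calls): one P/M/A call per probe per sample, plus a
# probe -> gene map (many-to-one) and a sample -> age-group map. A gene's
# expression score in a group is the fraction of its probe x sample cells
# called expressed; scores weight the edges of a static interactome to give
# one weighted network per age group.

#' Detection-call matrix with probe and sample maps
#'
#' @param calls a character matrix (probes in rows, samples in columns)
#'   with entries `"P"` (present), `"M"` (marginal) or `"A"` (absent).
#' @param probe_to_gene named character vector mapping every probe (names)
#'   to a gene identifier; many probes may map to one gene.
#' @param sample_to_group named character vector mapping every sample
#'   (names) to an age-group label.
#' @return an object of class `detection_calls`.
#' @export
detection_calls <- function(calls, probe_to_gene, sample_to_group) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("`calls` must have probe rownames and sample colnames")
  }
  bad <- !(calls %in% c("P", "M", "A"))
  if (any(bad)) {
    stop(sprintf("detection calls must be P, M or A; found '%s'",
                 calls[which(bad)[1]]))
  }
  missing_probe <- setdiff(rownames(calls), names(probe_to_gene))
  if (length(missing_probe) > 0) {
    stop(sprintf("probe '%s' has no gene mapping", missing_probe[1]))
  }
  missing_sample <- setdiff(colnames(calls), names(sample_to_group))
  if (length(missing_sample) > 0) {
    stop(sprintf("sample '%s' has no group label", missing_sample[1]))
  }
  structure(list(calls = calls,
                 probe_to_gene = probe_to_gene[rownames(calls)],
                 sample_to_group = sample_to_group[colnames(calls)]),
            class = "detection_calls")
}

#' @export
print.detection_calls <- function(x, ...) {
  cat(sprintf(
    "detection_calls: %d probes x %d samples (%d genes, %d groups)\n",
    nrow(x$calls), ncol(x$calls),
    length(unique(x$probe_to_gene)),
    length(unique(x$sample_to_group))))
  invisible(x)
}

#' Per-gene, per-group expression scores
#'
#' For a gene with `q` probes and a group with `y` samples, the score is
#' the fraction of the `q * y` probe x sample cells called expressed. All
#' cells are pooled; there is no per-sample majority step. `"P"` counts as
#' expressed, `"A"` does not, and `"M"` (marginal) counts according to
#' `marginal_as_expressed` (default: not expressed, the conservative
#' choice).
#'
#' @param m a [detection_calls()] object.
#' @param marginal_as_expressed should marginal calls score 1 (default
#'   `FALSE`, scoring 0)?
#' @return a data.frame with columns `gene`, `group`, `score` (in
#'   `[0, 1]`), one row per gene x group combination, sorted.
#' @examples
#' calls <- matrix("P", 4, 3,
#'                 dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
#' calls[1, 1:2] <- "A"; calls[2, 1:2] <- "A"
#' m <- detection_calls(calls,
#'                      setNames(rep("v2", 4), paste0("p", 1:4)),
#'                      setNames(rep("35", 3), paste0("s", 1:3)))
#' expression_scores(m) # 8 of 12 cells expressed: score 8/12
#' @export
expression_scores <- function(m, marginal_as_expressed = FALSE) {
  stopifnot(inherits(m, "detection_calls"))
  expressed <- m$calls == "P"
  if (marginal_as_expressed) expressed <- expressed | m$calls == "M"
  genes <- sort(unique(unname(m$probe_to_gene)))
  groups <- sort(unique(unname(m$sample_to_group)))
  out <- expand.grid(gene = genes, group = groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$score <- NA_real_
  for (i in seq_len(nrow(out))) {
    pr <- names(m$probe_to_gene)[m$probe_to_gene == out$gene[i]]
    sa <- names(m$sample_to_group)[m$sample_to_group == out$group[i]]
    cells <- expressed[pr, sa, drop = FALSE]
    out$score[i] <- sum(cells) / length(cells)
  }
  out[order(out$gene, out$group), , drop = FALSE]
}

# internal: named score lookup vector for one group
score_lookup <- function(scores, group) {
  sub <- scores[scores$group == group, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop(sprintf("no expression scores for group '%s'", group))
  }
  stats::setNames(sub$score, sub$gene)
}

#' Build the dynamic weighted network for one age group
#'
#' An edge of the static interactome is kept when both endpoint genes have
#' a nonzero expression score in the group (scores above
#' `presence_threshold`, exclusive; the default 0 keeps any expressed
#' gene, `0.5` imposes a majority rule). Kept edges are weighted by the
#' arithmetic mean `(s_u + s_v) / 2` or the geometric mean
#' `sqrt(s_u * s_v)` of the endpoint scores; the failure probability is
#' `1 - weight`. Genes without a score in the group are treated as
#' unexpressed and their edges dropped (with a message).
#'
#' @param static a [weighted_network()] giving the interactome topology
#'   (weights ignored).
#' @param scores a data.frame from [expression_scores()].
#' @param group the age-group label to build.
#' @param mean_kind `"arithmetic"` (default) or `"geometric"`.
#' @param presence_threshold exclusive lower bound on endpoint scores for
#'   edge presence (default 0).
#' @return a [weighted_network()] whose node set is the endpoints of the
#'   kept edges.
#' @export
build_dynamic_network <- function(static, scores, group,
                                  mean_kind = c("arithmetic", "geometric"),
                                  presence_threshold = 0) {
  stopifnot(inherits(static, "weighted_network"))
  mean_kind <- match.arg(mean_kind)
  lk <- score_lookup(scores, group)
  e <- static$edges
  su <- unname(lk[e$u])
  sv <- unname(lk[e$v])
  unmapped <- unique(c(e$u[is.na(su)], e$v[is.na(sv)]))
  if (length(unmapped) > 0) {
    message(sprintf(
      "%d node(s) without a score in group '%s' treated as unexpressed",
      length(unmapped), group))
  }
  su[is.na(su)] <- 0
  sv[is.na(sv)] <- 0
  keep <- su > presence_threshold & sv > presence_threshold
  if (!any(keep)) {
    stop(sprintf("no edges survive in group '%s'", group))
  }
  w <- if (mean_kind == "arithmetic") (su[keep] + sv[keep]) / 2 else
    sqrt(su[keep] * sv[keep])
  weighted_network(data.frame(u = e$u[keep], v = e$v[keep], weight = w,
                              stringsAsFactors = FALSE))
}

#' Build dynamic networks for every age group
#'
#' @inheritParams build_dynamic_network
#' @return a named list of [weighted_network()]s, one per group present in
#'   `scores`.
#' @export
build_dynamic_networks <- function(static, scores,
                                   mean_kind = c("arithmetic", "geometric"),
                                   presence_threshold = 0) {
  mean_kind <- match.arg(mean_kind)
  groups <- sort(unique(scores$group))
  stats::setNames(
    lapply(groups, function(g)
      build_dynamic_network(static, scores, g, mean_kind,
                            presence_threshold)),
    groups)
}

#' Simulate a detection-call matrix
#'
#' Emulates the statistical structure of presence/absence calls on
#' multi-probe microarray data: each probe x sample cell of gene `g` in
#' group `a` is called present with probability `expr_prob[g, a]`, absent
#' otherwise, and independently flipped to marginal with probability
#' `marginal_rate`. Deterministic given `seed`.
#'
#' @param n_genes number of genes (named `g1 ... gN`).
#' @param probes_per_gene probes per gene.
#' @param samples_per_group named integer vector: samples per group label.
#' @param expr_prob per-gene, per-group presence probability: a single
#'   number, or a matrix with `n_genes` rows and one column per group.
#' @param marginal_rate probability that a call is downgraded to marginal.
#' @param seed integer RNG seed.
#' @return a [detection_calls()] object.
#' @export
simulate_detection_calls <- function(n_genes, probes_per_gene,
                                     samples_per_group, expr_prob,
                                     marginal_rate = 0, seed = 1L) {
  if (is.null(names(samples_per_group))) {
    stop("`samples_per_group` must be a named vector of counts")
  }
  genes <- sprintf("g%d", seq_len(n_genes))
  groups <- names(samples_per_group)
  if (is.matrix(expr_prob)) {
    stopifnot(nrow(expr_prob) == n_genes,
              ncol(expr_prob) == length(groups))
  } else {
    expr_prob <- matrix(expr_prob, n_genes, length(groups))
  }
  if (any(expr_prob < 0 | expr_prob > 1) ||
      marginal_rate < 0 || marginal_rate > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  dimnames(expr_prob) <- list(genes, groups)
  probes <- sprintf("%s_p%d", rep(genes, each = probes_per_gene),
                    seq_len(probes_per_gene))
  probe_to_gene <- stats::setNames(rep(genes, each = probes_per_gene),
                                   probes)
  samples <- unlist(lapply(groups, function(g)
    sprintf("%s_s%d", g, seq_len(samples_per_group[[g]]))))
  sample_to_group <- stats::setNames(
    rep(groups, times = unname(samples_per_group)), samples)

  calls <- with_seed(seed, {
    mat <- matrix("A", length(probes), length(samples),
                  dimnames = list(probes, samples))
    for (j in seq_along(samples)) {
      p <- expr_prob[probe_to_gene[probes], sample_to_group[samples[j]]]
      present <- stats::runif(length(probes)) < p
      mat[present, j] <- "P"
    }
    if (marginal_rate > 0) {
      flip <- matrix(stats::runif(length(mat)) < marginal_rate,
                     nrow(mat), ncol(mat))
      mat[flip] <- "M"
    }
    mat
  })
  detection_calls(calls, probe_to_gene, sample_to_group)
}

#' Read detection-call inputs from TSV files
#'
#' `read_call_matrix()` expects probes in rows and samples in columns with
#' a header line; `read_two_column_map()` reads a headerless two-column TSV
#' (key, value), used for probe -> gene and sample -> group maps.
#'
#' @param path file path.
#' @return `read_call_matrix()`: a character matrix.
#'   `read_two_column_map()`: a named character vector.
#' @export
read_call_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          row.names = 1, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  as.matrix(df)
}

#' @rdname read_call_matrix
#' @export
read_two_column_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) != 2) stop(sprintf("%s: expected exactly 2 columns", path))
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}
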