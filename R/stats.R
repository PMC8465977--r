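# Enrichment of control categories in a reference gene set, transition
# counting between consecutive age periods, and unique-critical-set
# computation.

#' A named gene set
#'
#' @param name label for the set.
#' @param members character vector of gene identifiers (deduplicated).
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' Read a gene set file (one identifier per line, `#` comments)
#'
#' @param path file path.
#' @param name set label; defaults to the file name.
#' @return a [gene_set()].
#' @export
read_gene_set <- function(path, name = basename(path)) {
  raw <- readLines(path)
  ids <- trimws(raw[!grepl("^\\s*(#|$)", raw)])
  gene_set(name, ids)
}

#' Exact two-tailed Fisher test for a 2x2 table
#'
#' Two-sided p-value for the table `[[a, b], [c, d]]`: the sum of the
#' probabilities of all tables with the observed margins whose
#' hypergeometric probability does not exceed that of the observed table
#' (within relative tolerance 1e-7).
#'
#' @param a,b,c,d non-negative integer cell counts; at least one margin
#'   must be positive.
#' @return the two-tailed p-value in `(0, 1]`.
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || anyNA(counts)) {
    stop("all cell counts must be non-negative")
  }
  if (sum(counts) == 0) stop("at least one margin must be positive")
  tab <- matrix(as.integer(round(counts)), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Enrichment of a control category in a reference gene set
#'
#' With a universe of `N` nodes of which `N_A` belong to the reference set,
#' and a category of `N_S` nodes of which `N_AS` belong to the reference,
#' the enrichment is `E = ln(f_AS / f_A)` with `f_A = N_A / N` and
#' `f_AS = N_AS / N_S`; positive values indicate over-representation,
#' negative values depletion, and `N_AS = 0` gives `-Inf` (the p-value is
#' still computed). Significance is the two-tailed Fisher exact test on the
#' 2x2 table (in category vs not) x (in reference vs not).
#'
#' @param category character vector of nodes (e.g. the critical set); must
#'   be a subset of `universe` and nonempty.
#' @param reference a [gene_set()]; its intersection with the universe must
#'   be nonempty.
#' @param universe character vector of all nodes of the analysed network.
#' @param pseudo add 0.5 to every cell when computing `E` only (a plotting
#'   convenience for zero cells; default off). The p-value always uses the
#'   raw counts.
#' @return an object of class `enrichment_result` with fields `enrichment`,
#'   `p_value`, `table` (2x2 matrix), `f_A`, `f_AS` and the four counts.
#' @examples
#' eg <- control_enrichment(paste0("n", 1:20),
#'                          gene_set("ref", paste0("n", c(1:5, 21:25))),
#'                          paste0("n", 1:100))
#' eg$enrichment # log(0.25 / 0.10)
#' @export
control_enrichment <- function(category, reference, universe,
                               pseudo = FALSE) {
  stopifnot(inherits(reference, "gene_set"))
  universe <- unique(as.character(universe))
  category <- unique(as.character(category))
  if (length(setdiff(category, universe)) > 0) {
    stop("`category` must be a subset of `universe`")
  }
  N <- length(universe)
  N_S <- length(category)
  ref_in <- intersect(reference$members, universe)
  N_A <- length(ref_in)
  N_AS <- length(intersect(category, ref_in))
  if (N_S == 0) {
    stop(errorCondition("enrichment undefined: empty category",
                        class = c("probdom_undefined_enrichment", "error")))
  }
  if (N_A == 0) {
    stop(errorCondition(
      "enrichment undefined: reference set does not intersect the universe",
      class = c("probdom_undefined_enrichment", "error")))
  }
  f_A <- N_A / N
  f_AS <- N_AS / N_S
  tab <- matrix(c(N_AS, N_S - N_AS,
                  N_A - N_AS, N - N_S - (N_A - N_AS)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_category", "not_category"),
                                c("in_reference", "not_reference")))
  E <- if (pseudo) {
    pt <- tab + 0.5
    log((pt[1, 1] / sum(pt[1, ])) / (sum(pt[, 1]) / sum(pt)))
  } else if (N_AS == 0) -Inf else log(f_AS / f_A)
  p <- fisher_exact_two_tailed(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  structure(list(enrichment = E, p_value = p, table = tab,
                 f_A = f_A, f_AS = f_AS,
                 N = N, N_S = N_S, N_A = N_A, N_AS = N_AS),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: E = %.4f (f_AS = %.4f, f_A = %.4f), p = %.4g\n",
    x$enrichment, x$f_AS, x$f_A, x$p_value))
  invisible(x)
}

#' Enrichment report over groups and control categories
#'
#' @param classifications named list of `control_classification` objects
#'   (names are the group labels).
#' @param reference a [gene_set()].
#' @return a data.frame with columns `group`, `category`, `N`, `N_S`,
#'   `N_A`, `N_AS`, `E`, `p`.
#' @export
enrichment_table <- function(classifications, reference) {
  rows <- list()
  for (g in names(classifications)) {
    cls <- classifications[[g]]
    universe <- c(cls$critical, cls$intermittent, cls$redundant)
    for (cat in c("critical", "intermittent", "redundant")) {
      nodes <- cls[[cat]]
      if (length(nodes) == 0) next
      er <- control_enrichment(nodes, reference, universe)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, category = cat, N = er$N, N_S = er$N_S,
        N_A = er$N_A, N_AS = er$N_AS, E = er$enrichment, p = er$p_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Turnover of the critical set between two consecutive periods
#'
#' `in_count` is the number of nodes newly critical in the second period,
#' `out_count` the number that lost the critical role, and
#' `changes = in_count + out_count`.
#'
#' @param critical_t1,critical_t2 character vectors of critical nodes at
#'   the earlier and later period.
#' @return a list with `changes`, `in_count`, `out_count`, `in_nodes`,
#'   `out_nodes`.
#' @examples
#' transition_counts(c("p1", "p2", "p3"), c("p1", "p2", "p4"))
#' @export
transition_counts <- function(critical_t1, critical_t2) {
  critical_t1 <- unique(as.character(critical_t1))
  critical_t2 <- unique(as.character(critical_t2))
  ins <- sort(setdiff(critical_t2, critical_t1))
  outs <- sort(setdiff(critical_t1, critical_t2))
  list(changes = length(ins) + length(outs),
       in_count = length(ins), out_count = length(outs),
       in_nodes = ins, out_nodes = outs)
}

#' Transition report across an ordered sequence of periods
#'
#' @param critical_sets named list of critical sets in period order.
#' @return a data.frame with columns `group_pair`, `in`, `out`, `changes`.
#' @export
transition_table <- function(critical_sets) {
  if (length(critical_sets) < 2) stop("need at least two periods")
  labs <- names(critical_sets)
  rows <- lapply(seq_len(length(critical_sets) - 1L), function(i) {
    tc <- transition_counts(critical_sets[[i]], critical_sets[[i + 1L]])
    data.frame(group_pair = sprintf("%s vs %s", labs[i], labs[i + 1L]),
               `in` = tc$in_count, out = tc$out_count,
               changes = tc$changes, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Critical nodes unique to each group, with all intersection regions
#'
#' For each group, the unique set contains the nodes critical in that group
#' and in no other. All Venn-style intersection regions (membership
#' patterns over the groups) are counted as well.
#'
#' @param per_group named list (1 to 6 groups) of character vectors.
#' @return a list with `unique` (named list of character vectors) and
#'   `regions` (data.frame with columns `region` — `+`-separated group
#'   labels — and `count`).
#' @export
unique_criticals <- function(per_group) {
  k <- length(per_group)
  if (k < 1) stop("need at least one group")
  if (k > 6) stop("more than 6 groups refused (2^k intersection regions)")
  if (is.null(names(per_group)) || any(!nzchar(names(per_group)))) {
    stop("`per_group` must be a named list")
  }
  per_group <- lapply(per_group, function(x) unique(as.character(x)))
  labs <- names(per_group)
  uniq <- stats::setNames(lapply(seq_len(k), function(i) {
    others <- unlist(per_group[-i], use.names = FALSE)
    sort(setdiff(per_group[[i]], others))
  }), labs)
  all_nodes <- unique(unlist(per_group, use.names = FALSE))
  membership <- vapply(per_group, function(s) all_nodes %in% s,
                       logical(length(all_nodes)))
  if (length(all_nodes) == 1L) membership <- matrix(membership, nrow = 1)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k),
                          KEEP.OUT.ATTRS = FALSE)[-1, , drop = FALSE]
  region <- apply(patterns, 1, function(p)
    paste(labs[as.logical(p)], collapse = "+"))
  count <- apply(patterns, 1, function(p) {
    if (length(all_nodes) == 0) return(0L)
    sum(apply(membership, 1, function(row) all(row == as.logical(p))))
  })
  list(unique = uniq,
       regions = data.frame(region = region, count = as.integer(count),
                            stringsAsFactors = FALSE))
}
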