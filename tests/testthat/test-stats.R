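test_that("enrichment follows the log-ratio definition", {
  universe <- paste0("n", 1:100)
  reference <- gene_set("ref", paste0("n", c(1:5, 21:25)))
  # N = 100, N_A = 10, N_S = 20, N_AS = 5: E = ln(0.25 / 0.10)
  category <- paste0("n", c(1:5, 31:45))
  er <- control_enrichment(category, reference, universe)
  expect_equal(er$N_AS, 5)
  expect_equal(er$enrichment, log(2.5))
  expect_equal(sum(er$table), 100)
  expect_equal(rowSums(er$table)[[1]], 20)
  expect_equal(colSums(er$table)[[1]], 10)

  # proportional representation: E = 0, p = 1
  prop <- paste0("n", c(1, 21, 31:48)) # 2 of 20 in reference = f_A
  er0 <- control_enrichment(prop, reference, universe)
  expect_equal(er0$enrichment, 0)
  expect_equal(er0$p_value, 1)

  # empty overlap gives -Inf with a finite p-value
  none <- paste0("n", 31:40)
  ern <- control_enrichment(none, reference, universe)
  expect_identical(ern$enrichment, -Inf)
  expect_true(ern$p_value > 0 && ern$p_value <= 1)
  # pseudo-count variant stays finite
  expect_true(is.finite(
    control_enrichment(none, reference, universe, pseudo = TRUE)$enrichment))

  expect_error(control_enrichment(character(), reference, universe),
               class = "probdom_undefined_enrichment")
  expect_error(control_enrichment("n1", gene_set("empty", "zzz"), universe),
               class = "probdom_undefined_enrichment")
  expect_error(control_enrichment("not_there", reference, universe),
               "subset")
})

test_that("enrichment sign tracks over- and under-representation", {
  set.seed(61)
  universe <- paste0("g", 1:60)
  reference <- gene_set("ref", paste0("g", 1:15))
  for (rep in 1:25) {
    category <- sample(universe, sample(5:30, 1))
    er <- control_enrichment(category, reference, universe)
    if (is.finite(er$enrichment)) {
      expect_equal(er$enrichment > 0, er$f_AS > er$f_A)
      expect_equal(er$enrichment == 0, er$f_AS == er$f_A)
    } else {
      expect_equal(er$N_AS, 0)
    }
  }
})

test_that("two-tailed Fisher p agrees with hypergeometric enumeration", {
  expect_equal(fisher_exact_two_tailed(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_two_tailed(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-10)
  expect_equal(fisher_exact_two_tailed(3, 1, 1, 3), 0.4857143,
               tolerance = 1e-6)
  set.seed(71)
  for (rep in 1:60) {
    cells <- as.vector(stats::rmultinom(1, sample(8:40, 1), rep(1 / 4, 4)))
    p_pkg <- fisher_exact_two_tailed(cells[1], cells[2], cells[3], cells[4])
    p_ora <- fisher_oracle(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p_pkg, p_ora, tolerance = 1e-7)
  }
  expect_error(fisher_exact_two_tailed(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_two_tailed(0, 0, 0, 0), "positive")
})

test_that("Fisher p is symmetric under row and column swaps", {
  set.seed(81)
  for (rep in 1:20) {
    x <- sample(0:12, 4, replace = TRUE)
    if (sum(x) == 0) next
    p <- fisher_exact_two_tailed(x[1], x[2], x[3], x[4])
    expect_equal(fisher_exact_two_tailed(x[3], x[4], x[1], x[2]), p)
    expect_equal(fisher_exact_two_tailed(x[2], x[1], x[4], x[3]), p)
  }
})

test_that("transition counts decompose into INs and OUTs", {
  tc <- transition_counts(c("p1", "p2", "p3"), c("p1", "p2", "p4"))
  expect_equal(tc$changes, 2)
  expect_equal(tc$in_count, 1)
  expect_equal(tc$out_count, 1)
  expect_equal(tc$in_nodes, "p4")
  expect_equal(tc$out_nodes, "p3")

  same <- transition_counts(c("x", "y"), c("y", "x"))
  expect_equal(same$changes, 0)

  disj <- transition_counts(c("a", "b"), c("c", "d", "e"))
  expect_equal(disj$changes, 5)
  expect_equal(disj$in_count, 3)
  expect_equal(disj$out_count, 2)

  # in/out are mirror images
  set.seed(91)
  for (rep in 1:10) {
    x <- sample(letters, 8)
    y <- sample(letters, 6)
    expect_equal(transition_counts(x, y)$in_count,
                 transition_counts(y, x)$out_count)
  }
})

test_that("unique criticals and intersection regions partition the union", {
  res <- unique_criticals(list(A = c("p1", "p2"), B = c("p2", "p3")))
  expect_equal(res$unique$A, "p1")
  expect_equal(res$unique$B, "p3")
  expect_equal(res$regions$count[res$regions$region == "A+B"], 1L)
  expect_equal(sum(res$regions$count), 3L)

  idem <- unique_criticals(stats::setNames(
    rep(list(c("x", "y", "z")), 4), c("a", "b", "c", "d")))
  expect_true(all(lengths(idem$unique) == 0))
  expect_equal(idem$regions$count[idem$regions$region == "a+b+c+d"], 3L)

  disj <- unique_criticals(list(g1 = c("m", "n"), g2 = c("o")))
  expect_equal(disj$unique$g1, c("m", "n"))
  expect_equal(disj$unique$g2, "o")

  expect_error(unique_criticals(stats::setNames(
    rep(list("x"), 7), paste0("g", 1:7))), "6 groups")
})

test_that("report tables assemble across groups", {
  q <- coverage_query(0.5)
  cls <- list(young = classify_controls(star_net(4, 0.9), q),
              old = classify_controls(path3(0.9), q))
  ref <- gene_set("ageing", c("hub", "leaf1", "b"))
  tab <- enrichment_table(cls, ref)
  expect_true(all(c("group", "category", "E", "p") %in% names(tab)))
  expect_true(all(tab$p > 0 & tab$p <= 1))

  tt <- transition_table(list(t1 = c("p1", "p2", "p3"),
                              t2 = c("p1", "p2", "p4")))
  expect_equal(tt$changes, 2)
  expect_equal(tt$group_pair, "t1 vs t2")
  expect_error(transition_table(list(a = "x")), "at least two")
})

test_that("gene set files ignore comments and duplicates", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# known ageing genes", "ATM", "CDKN1A", "", "ATM"), tmp)
  gs <- read_gene_set(tmp, name = "test")
  expect_equal(sort(gs$members), c("ATM", "CDKN1A"))
})
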