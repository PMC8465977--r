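make_worked_example <- function() {
  # gene v2: 4 probes x 3 samples in the "35" group, 8 of 12 cells present
  calls <- matrix("P", 4, 3,
                  dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
  calls[1, 1:2] <- "A"
  calls[2, 1:2] <- "A"
  detection_calls(calls,
                  setNames(rep("v2", 4), paste0("p", 1:4)),
                  setNames(rep("35", 3), paste0("s", 1:3)))
}

test_that("expression score pools probe x sample cells", {
  sc <- expression_scores(make_worked_example())
  expect_equal(sc$score, 8 / 12)
  # displayed at 2 d.p. by truncation this is 0.66
  expect_equal(floor(sc$score * 100) / 100, 0.66)

  m <- make_worked_example()
  m$calls[] <- "A"
  expect_equal(expression_scores(m)$score, 0)
  m$calls[] <- "P"
  expect_equal(expression_scores(m)$score, 1)
})

test_that("marginal calls score 0 by default and 1 on request", {
  calls <- matrix(c("P", "M", "A", "M"), 2, 2,
                  dimnames = list(c("p1", "p2"), c("s1", "s2")))
  m <- detection_calls(calls, setNames(rep("g", 2), c("p1", "p2")),
                       setNames(rep("a", 2), c("s1", "s2")))
  expect_equal(expression_scores(m)$score, 1 / 4)
  expect_equal(expression_scores(m, marginal_as_expressed = TRUE)$score,
               3 / 4)
})

test_that("scores are invariant to probe and sample ordering", {
  set.seed(21)
  m <- simulate_detection_calls(5, 3, c(young = 4, old = 4),
                                expr_prob = 0.6, marginal_rate = 0.1,
                                seed = 77)
  sc <- expression_scores(m)
  perm <- detection_calls(
    m$calls[sample(nrow(m$calls)), sample(ncol(m$calls))],
    m$probe_to_gene, m$sample_to_group)
  expect_equal(expression_scores(perm), sc, ignore_attr = TRUE)
})

test_that("dynamic networks keep only edges between expressed genes", {
  static <- weighted_network(data.frame(
    u = c("v1", "v1", "v2"), v = c("v2", "v3", "v3")))
  scores <- data.frame(gene = rep(c("v1", "v2", "v3"), each = 1),
                       group = "35",
                       score = c(1.0, 8 / 12, 0))
  dyn <- build_dynamic_network(static, scores, "35")
  # v3 has score 0: both of its edges are gone
  expect_equal(nrow(dyn$edges), 1)
  expect_equal(dyn$edges$u, "v1")
  expect_equal(dyn$edges$v, "v2")
  expect_equal(dyn$edges$weight, (1 + 8 / 12) / 2)
  expect_equal(dyn$edges$failure, 1 - (1 + 8 / 12) / 2)

  geo <- build_dynamic_network(static, scores, "35", "geometric")
  expect_equal(geo$edges$weight, sqrt(8 / 12))

  expect_error(build_dynamic_network(static, scores, "35", "harmonic"))

  # a gene missing from the score table is treated as unexpressed
  scores2 <- scores[scores$gene != "v2", ]
  expect_message(
    expect_error(build_dynamic_network(static, scores2, "35"),
                 "no edges survive"),
    "unexpressed")
})

test_that("presence threshold can impose a majority rule", {
  static <- weighted_network(data.frame(u = "v1", v = "v2"))
  scores <- data.frame(gene = c("v1", "v2"), group = "a",
                       score = c(0.9, 0.4))
  expect_equal(nrow(build_dynamic_network(static, scores, "a")$edges), 1)
  expect_error(build_dynamic_network(static, scores, "a",
                                     presence_threshold = 0.5),
               "no edges survive")
})

test_that("arithmetic mean dominates geometric mean edgewise", {
  set.seed(31)
  m <- simulate_detection_calls(30, 3, c(g1 = 5, g2 = 5),
                                expr_prob = matrix(runif(60, 0.2, 1), 30, 2),
                                seed = 99)
  sc <- expression_scores(m)
  genes <- unique(sc$gene)
  pairs <- t(combn(genes, 2))[sample(choose(length(genes), 2), 40), ]
  static <- weighted_network(data.frame(u = pairs[, 1], v = pairs[, 2]))
  for (grp in c("g1", "g2")) {
    am <- tryCatch(build_dynamic_network(static, sc, grp, "arithmetic"),
                   error = function(e) NULL)
    gm <- tryCatch(build_dynamic_network(static, sc, grp, "geometric"),
                   error = function(e) NULL)
    if (is.null(am)) next
    expect_identical(am$edges[, c("u", "v")], gm$edges[, c("u", "v")])
    expect_true(all(am$edges$weight >= gm$edges$weight - 1e-12))
    # dynamic edges are a subset of the static interactome
    key <- function(e) paste(e$u, e$v)
    expect_true(all(key(am$edges) %in% key(static$edges)))
  }
})

test_that("simulated calls recover the generating probabilities", {
  # q * y = 40 * 30 = 1200 cells per gene: binomial se ~ 0.013
  m <- simulate_detection_calls(4, 40, c(grp = 30), expr_prob = 0.7,
                                seed = 13)
  sc <- expression_scores(m)
  se <- sqrt(0.7 * 0.3 / 1200)
  expect_true(all(abs(sc$score - 0.7) <= 3 * se))

  # degenerate probabilities
  all_p <- simulate_detection_calls(3, 2, c(a = 2), expr_prob = 1, seed = 1)
  expect_true(all(all_p$calls == "P"))
  expect_equal(expression_scores(all_p)$score, rep(1, 3))
  all_a <- simulate_detection_calls(3, 2, c(a = 2), expr_prob = 0, seed = 1)
  expect_true(all(all_a$calls == "A"))

  # determinism
  m2 <- simulate_detection_calls(4, 40, c(grp = 30), expr_prob = 0.7,
                                 seed = 13)
  expect_identical(m$calls, m2$calls)
})

test_that("call matrices validate their categories and maps", {
  calls <- matrix("P", 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  p2g <- setNames(c("g1", "g1"), c("p1", "p2"))
  s2g <- setNames(c("a", "a"), c("s1", "s2"))
  expect_s3_class(detection_calls(calls, p2g, s2g), "detection_calls")
  bad <- calls
  bad[1, 1] <- "X"
  expect_error(detection_calls(bad, p2g, s2g), "P, M or A")
  expect_error(detection_calls(calls, p2g[1], s2g), "no gene mapping")
  expect_error(detection_calls(calls, p2g, s2g[1]), "no group label")
})
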