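test_that("leaf rule marks hubs with two coverable leaves as critical", {
  q <- coverage_query(0.5)
  expect_equal(rule_critical_leaves(star_net(3, 0.9), q), "hub")
  # leaves below the threshold do not qualify
  expect_equal(rule_critical_leaves(star_net(3, 0.3), q), character())
  # a single edge gives each endpoint only one degree-1 neighbour
  expect_equal(rule_critical_leaves(single_edge(0.9), q), character())
  # exactly two qualifying leaves among several non-qualifying ones
  mixed <- weighted_network(data.frame(
    u = "hub", v = sprintf("leaf%d", 1:4),
    weight = c(0.9, 0.8, 0.2, 0.1)))
  expect_equal(rule_critical_leaves(mixed, q), "hub")
})

test_that("covered rule marks fully-covered neighbours of criticals redundant", {
  q <- coverage_query(0.5)
  star <- star_net(3, 0.9)
  expect_equal(rule_redundant_covered(star, q, known_critical = "hub"),
               c("leaf1", "leaf2", "leaf3"))
  # coverage below theta blocks the rule
  weak <- star_net(3, 0.3)
  expect_equal(rule_redundant_covered(weak, q, known_critical = "hub"),
               character())
  # an unclassified neighbour blocks the rule
  p3 <- path3(0.9)
  expect_equal(rule_redundant_covered(p3, q, known_critical = "b",
                                      unclassified = c("a", "c")),
               c("a", "c"))
  expect_equal(rule_redundant_covered(p3, q, known_critical = character()),
               character())
})

test_that("uncoverable rule marks isolated and weakly-connected nodes critical", {
  q <- coverage_query(0.5)
  iso <- weighted_network(nodes = c("x", "y"))
  expect_equal(rule_critical_uncoverable(iso, q), c("x", "y"))
  # two neighbours with failure 0.8 each: 1 - 0.64 = 0.36 < 0.5
  twonb <- weighted_network(data.frame(u = c("m", "m"), v = c("a", "b"),
                                       weight = 0.2))
  expect_true("m" %in% rule_critical_uncoverable(twonb, q))
  # one neighbour with failure 0.1: coverage 0.9 >= 0.5
  strong <- single_edge(0.9)
  expect_equal(rule_critical_uncoverable(strong, q), character())
})

test_that("preprocessing reaches the documented fixpoints", {
  q <- coverage_query(0.5)
  pre <- preprocess_controls(star_net(3, 0.9), q)
  expect_equal(pre$critical, "hub")
  expect_equal(pre$redundant, c("leaf1", "leaf2", "leaf3"))
  expect_equal(pre$lower_bound, 1)

  # nothing fires on a unit-weight 4-cycle
  pre <- preprocess_controls(cycle4(), q)
  expect_equal(pre$critical, character())
  expect_equal(pre$redundant, character())

  pre <- preprocess_controls(weighted_network(nodes = c("x", "y")), q)
  expect_equal(pre$critical, c("x", "y"))
  expect_equal(pre$lower_bound, 2)
})

test_that("classification matches enumeration on the worked examples", {
  q <- coverage_query(0.5)
  cls <- classify_controls(path3(), q)
  expect_equal(cls$critical, "b")
  expect_equal(cls$redundant, c("a", "c"))
  expect_equal(cls$pmds_size, 1)

  cls <- classify_controls(cycle4(), q)
  expect_equal(cls$intermittent, c("a", "b", "c", "d"))
  expect_equal(cls$pmds_size, 2)

  cls <- classify_controls(single_edge(0.4), q)
  expect_equal(cls$critical, c("a", "b"))
  expect_equal(cls$pmds_size, 2)
})

test_that("classification equals the enumeration oracle on random networks", {
  set.seed(202)
  for (rep in 1:50) {
    net <- random_er_network(sample(4:11, 1), sample(c(0.2, 0.4), 1))
    q <- coverage_query(sample(c(0.1, 0.3, 0.5, 0.7, 0.9), 1))
    o <- oracle_classify(net, q)
    cls <- classify_controls(net, q)
    expect_identical(cls$critical, o$critical)
    expect_identical(cls$intermittent, o$intermittent)
    expect_identical(cls$redundant, o$redundant)
    expect_equal(cls$pmds_size, o$size)
    # preprocessing is sound: rule output never contradicts the oracle
    expect_true(all(cls$preprocessed_critical %in% o$critical))
    expect_true(all(cls$preprocessed_redundant %in% o$redundant))
    expect_lte(cls$preprocessing_lower_bound, cls$pmds_size)
  }
})

test_that("preprocessing on, off and single-pass give identical partitions", {
  set.seed(303)
  for (rep in 1:15) {
    net <- random_er_network(12, 0.25)
    q <- coverage_query(sample(c(0.3, 0.5, 0.7), 1))
    a <- classify_controls(net, q)
    b <- classify_controls(net, q, preprocess = FALSE)
    c3 <- classify_controls(net, q, single_pass = TRUE)
    expect_same_partition(a, b)
    expect_same_partition(a, c3)
  }
})

test_that("the partition is independent of node input order", {
  set.seed(404)
  base <- data.frame(u = c("a", "b", "c", "a", "d"),
                     v = c("b", "c", "d", "d", "e"),
                     weight = c(0.7, 0.4, 0.9, 0.3, 0.6))
  q <- coverage_query(0.5)
  ref <- classify_controls(weighted_network(base), q)
  for (rep in 1:5) {
    perm <- base[sample(nrow(base)), ]
    flip <- sample(nrow(perm), 2)
    tmp <- perm$u[flip]
    perm$u[flip] <- perm$v[flip]
    perm$v[flip] <- tmp
    cls <- classify_controls(weighted_network(perm), q)
    expect_same_partition(ref, cls)
  }
})

test_that("classification tables and summaries round-trip", {
  q <- coverage_query(0.5)
  cls <- classify_controls(star_net(3, 0.9), q)
  df <- as.data.frame(cls)
  expect_setequal(df$node, c("hub", "leaf1", "leaf2", "leaf3"))
  expect_equal(df$category[df$node == "hub"], "critical")
  expect_equal(unique(df$preclassified[df$node != "hub"]), "covered")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_classification(cls, tmp)
  back <- read.table(tmp, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  expect_equal(back, df, ignore_attr = TRUE)
  s <- classification_summary(cls)
  expect_equal(s$pmds_size, 1)
  expect_equal(s$n_redundant, 3)
})
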