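test_that("score filtering is inclusive, stable and matches a linear scan", {
  rec <- data.frame(node_a = c("a", "b", "c"), node_b = c("x", "y", "z"),
                    combined_score = c(699L, 700L, 701L))
  expect_equal(filter_by_score(rec, 700)$combined_score, c(700L, 701L))
  expect_equal(filter_by_score(rec, 0), rec)

  set.seed(42)
  rnd <- data.frame(node_a = sprintf("a%d", 1:100),
                    node_b = sprintf("b%d", 1:100),
                    combined_score = sample(0:1000, 100, replace = TRUE))
  kept <- filter_by_score(rnd, 700)
  expect_equal(nrow(kept), sum(rnd$combined_score >= 700))
  expect_true(all(diff(match(kept$node_a, rnd$node_a)) > 0))
  expect_error(filter_by_score(rnd, 1001), "min_score")
})

test_that("network construction dedupes, prunes and types nodes correctly", {
  # symmetric duplicates collapse keeping the max score
  pp <- data.frame(node_a = c("p1", "p2"), node_b = c("p2", "p1"),
                   combined_score = c(800L, 900L))
  cp <- data.frame(node_a = "fA", node_b = "p1", combined_score = 750L)
  net <- build_master_network(pp, cp, "fA", character())
  e <- net$edges[net$edges$layer == "protein_protein", ]
  expect_equal(nrow(e), 1L)
  expect_equal(e$combined_score, 900L)

  # self-loops are removed; compounds off the whitelists drop with edges;
  # proteins isolated by that removal disappear
  pp2 <- data.frame(node_a = c("p1", "p2"), node_b = c("p1", "p3"),
                    combined_score = c(800L, 800L))
  cp2 <- data.frame(node_a = c("fA", "zz"), node_b = c("p2", "p9"),
                    combined_score = c(800L, 800L))
  net2 <- build_master_network(pp2, cp2, "fA", character())
  expect_false("p1" %in% net2$nodes$node)  # only a self-loop
  expect_false("p9" %in% net2$nodes$node)  # only linked to dropped compound
  expect_false("zz" %in% net2$nodes$node)
  expect_setequal(net2$nodes$node, c("p2", "p3", "fA"))

  # hand-enumerated toy graph
  net3 <- toy_network()
  expect_equal(nrow(net3$nodes), 11L)   # 6 proteins + 2 flavonoids + 3 drugs
  expect_equal(nrow(net3$edges), 12L)   # 6 pp + 6 cp
  expect_equal(sum(net3$nodes$kind == "protein"), 6L)

  # error paths
  expect_error(build_master_network(pp, cp, "fA", "fA"), "both whitelists")
  ppbad <- data.frame(node_a = "fA", node_b = "p1", combined_score = 800L)
  expect_error(build_master_network(ppbad, cp, "fA", character()),
               "protein-protein layer")
})

test_that("construction is order-independent and monotone in min_score", {
  set.seed(7)
  pp <- data.frame(node_a = sample(sprintf("p%d", 1:30), 60, TRUE),
                   node_b = sample(sprintf("p%d", 1:30), 60, TRUE),
                   combined_score = sample(0:1000, 60, TRUE))
  cp <- data.frame(node_a = sample(c("fA", "fB", "dX", "dY"), 30, TRUE),
                   node_b = sample(sprintf("p%d", 1:30), 30, TRUE),
                   combined_score = sample(0:1000, 30, TRUE))
  build <- function(pp, cp, ms) {
    build_master_network(filter_by_score(pp, ms), filter_by_score(cp, ms),
                         c("fA", "fB"), c("dX", "dY"))
  }
  n1 <- build(pp, cp, 500)
  perm <- sample(nrow(pp)); permc <- sample(nrow(cp))
  n2 <- build(pp[perm, ], cp[permc, ], 500)
  expect_equal(n1$nodes, n2$nodes)
  # identical up to duplicate resolution, which keeps the max score
  expect_equal(n1$edges, n2$edges)

  sizes <- vapply(c(0, 300, 700, 900), function(ms) {
    n <- build(pp, cp, ms)
    c(nrow(n$nodes), nrow(n$edges))
  }, numeric(2))
  expect_true(all(diff(sizes[1, ]) <= 0))
  expect_true(all(diff(sizes[2, ]) <= 0))

  # conservation: every surviving edge above threshold, every node degree >= 1
  n700 <- build(pp, cp, 700)
  expect_true(all(n700$edges$combined_score >= 700))
  deg <- table(c(n700$edges$node_a, n700$edges$node_b))
  expect_true(all(n700$nodes$node %in% names(deg)))
})

test_that("topology summary satisfies its formula invariants", {
  # triangle graph
  pp <- data.frame(node_a = c("p1", "p2", "p3"), node_b = c("p2", "p3", "p1"),
                   combined_score = 800L)
  cp <- data.frame(node_a = character(), node_b = character(),
                   combined_score = integer())
  tri <- build_master_network(pp, cp, character(), character())
  ts <- topology_summary(tri)
  expect_equal(ts$density, 1.0)
  expect_equal(ts$mean_degree, 2.0)
  expect_equal(ts$degree_sd, 0)

  # formula invariants on a generated graph, cross-checked against igraph
  net <- toy_network()
  ts2 <- topology_summary(net)
  expect_equal(ts2$density,
               2 * ts2$n_edges / (ts2$n_nodes * (ts2$n_nodes - 1)),
               tolerance = 1e-12)
  expect_equal(ts2$mean_degree, 2 * ts2$n_edges / ts2$n_nodes,
               tolerance = 1e-12)
  expect_equal(ts2$n_pp_edges + ts2$n_cp_edges, ts2$n_edges)
  g <- as_igraph(net)
  expect_equal(ts2$density, igraph::edge_density(g), tolerance = 1e-12)
  expect_equal(ts2$mean_degree, mean(igraph::degree(g)), tolerance = 1e-12)
})

test_that("target sets are exactly the protein neighbours by cp edges", {
  net <- toy_network()
  expect_equal(target_set(net, "fA"), c("p1", "p2"))
  expect_equal(target_set(net, "dZ"), "p6")
  expect_error(target_set(net, "nope"), "unknown compound")
  expect_error(target_set(net, "p1"), "not a compound")

  # brute-force oracle on a random toy graph
  set.seed(11)
  cp <- data.frame(node_a = sample(c("fA", "dX", "dY"), 40, TRUE),
                   node_b = sample(sprintf("p%d", 1:15), 40, TRUE),
                   combined_score = 900L)
  pp <- data.frame(node_a = "p1", node_b = "p2", combined_score = 900L)
  net2 <- build_master_network(pp, cp, "fA", c("dX", "dY"))
  for (cmp in c("fA", "dX", "dY")) {
    brute <- sort(unique(cp$node_b[cp$node_a == cmp]))
    expect_equal(target_set(net2, cmp), brute)
  }
})

test_that("rank-sum test matches exact enumeration and wilcox.test", {
  # identical distributions: fold ratio 1, p = 1
  net <- network_with_target_counts(c(3L, 5L), c(3L, 5L))
  cmpr <- target_count_comparison(net)
  expect_equal(cmpr$fold_ratio, 1.0)
  expect_equal(cmpr$wilcoxon_p, 1.0)

  # separated groups: exact permutation p = 0.1, normal approx close
  w <- wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12))
  p_exact <- oracle_ranksum_exact_p(c(1, 2, 3), c(10, 11, 12))
  expect_equal(p_exact, 0.1)
  expect_lt(abs(w$p_value - p_exact), 0.05)

  # agreement with stats::wilcox.test (normal approximation + correction)
  set.seed(3)
  for (i in 1:5) {
    x <- sample(1:20, 8, replace = TRUE)
    y <- sample(5:25, 10, replace = TRUE)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(wilcoxon_ranksum(x, y)$p_value, ref$p.value,
                 tolerance = 1e-10)
  }
})

test_that("target count comparison reports group means and fold ratio", {
  net <- network_with_target_counts(c(40L, 50L), c(10L, 20L, 15L))
  cmpr <- target_count_comparison(net)
  expect_equal(cmpr$flavonoid_mean, 45)
  expect_equal(cmpr$drug_mean, 15)
  expect_equal(cmpr$fold_ratio, 3)
  net1 <- network_with_target_counts(c(3L), c(4L, 5L))
  expect_error(target_count_comparison(net1), "at least 2")
})

test_that("network serialization round-trips through TSV", {
  net <- toy_network()
  ef <- tempfile(); nf <- tempfile()
  write_network(net, ef, nf)
  back <- read_network(ef, nf)
  expect_equal(back$edges, net$edges)
  expect_equal(back$nodes, net$nodes)
})
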