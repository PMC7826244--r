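test_that("degree_map handles stars, isolates, empty networks", {
  star <- build_network(rbind(c("C0", "L1"), c("C0", "L2"), c("C0", "L3"),
                              c("C0", "L4")))
  expect_identical(degree_map(star),
                   c(C0 = 4L, L1 = 1L, L2 = 1L, L3 = 1L, L4 = 1L))
  expect_identical(degree_map(build_network(NULL)),
                   stats::setNames(integer(0), character(0)))
  expect_identical(degree_map(build_network(NULL, "A")), c(A = 0L))
})

test_that("betweenness matches hand-computed values on small graphs", {
  p <- path_graph(c("A", "B", "C"))
  bc <- betweenness_centrality(p)
  expect_equal(bc, c(A = 0, B = 1, C = 0))
  expect_equal(betweenness_centrality(p, normalized = FALSE),
               c(A = 0, B = 1, C = 0))

  k5 <- complete_graph(sprintf("K%d", 1:5))
  expect_equal(unname(betweenness_centrality(k5)), rep(0, 5))

  # two triangles joined through bridge BB: every cross-clique geodesic
  # (3 x 3 pairs) passes through BB; anchors carry 8 pairs each
  g <- bridged_cliques()
  raw <- betweenness_centrality(g, normalized = FALSE)
  expect_equal(raw[["BB"]], 9)
  expect_equal(raw[["A1"]], 8)
  expect_equal(raw[["B1"]], 8)
  norm <- betweenness_centrality(g)
  expect_equal(norm[["BB"]], 9 / 15)
  expect_equal(norm[["A1"]], 8 / 15)
  expect_equal(sort(norm, decreasing = TRUE)[[2L]], 8 / 15)
})

test_that("Brandes agrees with igraph and stays in [0, 1] when normalized", {
  for (seed in 1:30) {
    g <- withr::with_seed(seed, rand_graph(15, 0.2))
    net <- suppressMessages(build_network(g$edges, extra_nodes = g$nodes))
    raw <- betweenness_centrality(net, normalized = FALSE)
    ref <- igraph::betweenness(net)
    expect_equal(raw, ref[order(names(ref))], tolerance = 1e-12)
    norm <- betweenness_centrality(net)
    expect_true(all(norm >= 0 & norm <= 1))
  }
})

test_that("tree identity: sum of raw BC equals sum of (d(s,t) - 1)", {
  for (seed in 1:30) {
    g <- withr::with_seed(seed, rand_tree(sample(5:20, 1L)))
    net <- build_network(g$edges)
    raw <- betweenness_centrality(net, normalized = FALSE)
    D <- fw_dist(g$nodes, g$edges)
    expect_equal(sum(raw), sum(D[upper.tri(D)] - 1), tolerance = 1e-9)
  }
})

test_that("closeness is the within-component mean-distance reciprocal", {
  k4 <- complete_graph(sprintf("K%d", 1:4))
  expect_equal(unname(closeness_centrality(k4)), rep(1, 4))
  p <- path_graph(c("A", "B", "C"))
  expect_equal(closeness_centrality(p), c(A = 2/3, B = 1, C = 2/3))
  expect_equal(closeness_centrality(build_network(NULL, "A")), c(A = 0))

  for (seed in 1:20) {
    g <- withr::with_seed(seed, rand_graph(10, 0.3))
    net <- suppressMessages(build_network(g$edges, extra_nodes = g$nodes))
    D <- fw_dist(g$nodes, g$edges)
    want <- vapply(g$nodes, function(v) {
      row <- D[v, ][is.finite(D[v, ])]
      if (length(row) <= 1L) 0 else (length(row) - 1) / sum(row)
    }, numeric(1))
    got <- closeness_centrality(net)
    expect_equal(got, want[sort(names(want))], tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("network_summary reports <K>, mspl and diameter over connected pairs", {
  p4 <- path_graph(c("A", "B", "C", "D"))
  s <- network_summary(p4)
  expect_equal(s$avg_degree, 1.5)
  expect_equal(s$mspl, 10 / 6)
  expect_identical(s$diameter, 3L)

  k4 <- complete_graph(sprintf("K%d", 1:4))
  s4 <- network_summary(k4)
  expect_equal(s4$avg_degree, 3)
  expect_equal(s4$mspl, 1)
  expect_identical(s4$diameter, 1L)

  expect_error(network_summary(build_network(NULL)), "at least one node")
  expect_warning(s0 <- network_summary(build_network(NULL, c("A", "B"))),
                 "edgeless")
  expect_equal(s0$mspl, 0)
  expect_equal(s0$diameter, 0)

  for (seed in 1:15) {
    g <- withr::with_seed(seed, rand_graph(10, 0.25))
    net <- suppressMessages(build_network(g$edges, extra_nodes = g$nodes))
    if (igraph::ecount(net) == 0) next
    D <- fw_dist(g$nodes, g$edges)
    d <- D[upper.tri(D)]
    d <- d[is.finite(d) & d > 0]
    s <- network_summary(net)
    expect_equal(s$mspl, mean(d))
    expect_equal(s$diameter, as.integer(max(d)))
    expect_equal(s$avg_degree, 2 * nrow(g$edges) / 10)
  }
})

test_that("complete-graph limit: BC 0, CC 1, diameter 1 for n >= 2", {
  for (n in 2:6) {
    kn <- complete_graph(sprintf("K%d", seq_len(n)))
    expect_equal(unname(betweenness_centrality(kn)), rep(0, n))
    expect_equal(unname(closeness_centrality(kn)), rep(1, n))
    expect_identical(network_summary(kn)$diameter, 1L)
  }
})

test_that("compute_node_metrics combines the three centralities consistently", {
  star <- build_network(rbind(c("C0", "L1"), c("C0", "L2"), c("C0", "L3")))
  m <- compute_node_metrics(star)
  expect_identical(m$symbol[1L], "C0")
  expect_equal(m[m$symbol == "C0", c("degree", "betweenness", "closeness")],
               data.frame(degree = 3L, betweenness = 1, closeness = 1),
               ignore_attr = TRUE)
  # leaf: distances 1 to center, 2 to each other leaf -> CC = 3/5
  expect_equal(m[m$symbol == "L1", "closeness"], 3 / 5)
  expect_equal(m[m$symbol == "L1", "betweenness"], 0)

  iso <- compute_node_metrics(build_network(NULL, "X"))
  expect_equal(iso,
               data.frame(symbol = "X", degree = 0L, betweenness = 0,
                          closeness = 0),
               ignore_attr = TRUE)

  for (seed in 1:10) {
    net <- generate_scale_free(30, 2, rng_seed = seed)
    m <- compute_node_metrics(net)
    ord <- order(m$symbol)
    expect_identical(stats::setNames(as.integer(m$degree[ord]),
                                     m$symbol[ord]),
                     degree_map(net))
    expect_equal(stats::setNames(m$betweenness[ord], m$symbol[ord]),
                 betweenness_centrality(net))
    expect_equal(stats::setNames(m$closeness[ord], m$symbol[ord]),
                 closeness_centrality(net))
    # ordering contract: descending degree, ties by symbol
    expect_identical(order(-m$degree, m$symbol), seq_len(nrow(m)))
  }
})

test_that("write_node_metrics emits a byte-stable 8-decimal TSV", {
  net <- bridged_cliques()
  m <- compute_node_metrics(net)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_node_metrics(m, f1)
  write_node_metrics(m, f2)
  lines <- readLines(f1)
  expect_identical(lines[1L], "symbol\tdegree\tbetweenness\tcloseness")
  expect_identical(length(lines), nrow(m) + 1L)
  expect_true(any(grepl("^BB\t2\t0\\.60000000\t", lines)))
  expect_identical(readLines(f1), readLines(f2))
})
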