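test_that("pearson matrix matches hand-computed correlations", {
  m <- rbind(a = c(1, 2, 3), b = c(6, 4, 2), c = c(1, 3, 2))
  rownames(m) <- paste0("hsa-mir-", rownames(m))
  ds <- tiny_dataset(m, 2, 1)
  r <- pearson_matrix(ds)
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(r["hsa-mir-a", "hsa-mir-b"], -1)
  expect_equal(r["hsa-mir-a", "hsa-mir-c"], 0.5)
  expect_equal(r, t(r))
  # zero-variance rows are flagged and excluded from edges
  m2 <- rbind(m, "hsa-mir-flat" = c(2, 2, 2))
  expect_warning(r2 <- pearson_matrix(tiny_dataset(m2, 2, 1)),
                 "zero-variance")
  g <- threshold_edges(r2, 0.4)
  expect_false("hsa-mir-flat" %in% igraph::V(g$graph)$name)
})

test_that("edge thresholding is strict and signed by default", {
  corr <- diag(3)
  dimnames(corr) <- list(paste0("m", 1:3), paste0("m", 1:3))
  corr["m1", "m2"] <- corr["m2", "m1"] <- 0.9       # exactly at threshold
  corr["m1", "m3"] <- corr["m3", "m1"] <- -0.95     # strong negative
  corr["m2", "m3"] <- corr["m3", "m2"] <- 0.95
  g <- threshold_edges(corr, 0.9)
  expect_equal(igraph::ecount(g$graph), 1)
  expect_setequal(igraph::V(g$graph)$name, c("m2", "m3"))
  g_abs <- threshold_edges(corr, 0.9, absolute = TRUE)
  expect_equal(igraph::ecount(g_abs$graph), 2)
  g_iso <- threshold_edges(corr, 0.9, keep_isolated = TRUE)
  expect_equal(igraph::vcount(g_iso$graph), 3)
  # a correlated triangle yields degree 2 everywhere
  tri <- matrix(0.95, 3, 3, dimnames = dimnames(corr)); diag(tri) <- 1
  gt <- threshold_edges(tri, 0.9)
  expect_equal(unname(igraph::degree(gt$graph)), c(2, 2, 2))
})

test_that("node metrics reproduce hand-derived values on canonical graphs", {
  path <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  dimnames(path) <- list(c("a", "b", "c"), c("a", "b", "c"))
  m <- node_metrics(graph_from_adjacency(path))
  expect_equal(m$betweenness, c(0, 1, 0))
  expect_equal(m$eccentricity, c(2, 1, 2))
  # 4-cycle: two shortest paths between opposite corners split the credit
  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- letters[1:4]
  m4 <- node_metrics(ring)
  expect_equal(m4$betweenness, rep(0.5, 4))
  # triangle + star + isolate
  adj <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  adj[cbind(c(1, 2, 1), c(2, 3, 3))] <- 1   # triangle a-b-c
  adj[4, 5] <- 1                            # star edge d-e
  adj <- pmax(adj, t(adj))
  m6 <- node_metrics(graph_from_adjacency(adj))
  expect_equal(m6$clustering_coefficient[1:3], rep(1, 3))
  expect_equal(m6$clustering_coefficient[4], 0)
  expect_equal(m6$eccentricity[6], 0)       # isolated node
})

test_that("all four metrics agree with the brute-force oracle on random graphs", {
  withr::with_seed(101, {
    for (i in 1:50) {
      n <- sample(4:12, 1)
      adj <- random_adjacency(n, runif(1, 0.15, 0.6))
      m <- node_metrics(graph_from_adjacency(adj))
      o <- oracle_graph_metrics(adj)
      expect_equal(m$degree, unname(o$degree))
      expect_equal(m$betweenness, o$betweenness, tolerance = 1e-10)
      expect_equal(m$eccentricity, o$eccentricity)
      expect_equal(m$clustering_coefficient, o$clustering_coefficient,
                   tolerance = 1e-10)
    }
  })
})

test_that("betweenness structure theorems hold", {
  # complete graph: no interior vertices on any shortest path
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(node_metrics(k5)$betweenness, rep(0, 5))
  # tree: unique paths, so total betweenness = sum over pairs of the
  # number of interior nodes on their path, i.e. sum of (d - 1) over
  # pairs at distance >= 2
  withr::with_seed(7, tree <- igraph::sample_tree(10))
  igraph::V(tree)$name <- letters[1:10]
  m <- node_metrics(tree)
  d <- igraph::distances(tree)
  interior_total <- sum(pmax(d[upper.tri(d)] - 1, 0))
  expect_equal(sum(m$betweenness), interior_total)
})

test_that("node summaries use population SD and respect the handshake lemma", {
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- letters[1:6]
  s <- summarize_nodes(graph_from_adjacency(as.matrix(igraph::as_adjacency_matrix(ring))))
  expect_equal(s["degree", "avg"], 2)
  expect_equal(s["degree", "sd"], 0)
  expect_equal(s["degree", "min"], s["degree", "max"])
  withr::with_seed(33, adj <- random_adjacency(9, 0.4))
  g <- graph_from_adjacency(adj)
  s2 <- summarize_nodes(g)
  expect_equal(s2["degree", "avg"],
               2 * igraph::ecount(g$graph) / igraph::vcount(g$graph))
  x <- node_metrics(g)$betweenness
  expect_equal(s2["betweenness", "sd"], sqrt(mean((x - mean(x))^2)))
  expect_error(summarize_nodes(data.frame()), "empty")
})

test_that("degree hub selection uses a strict fractional cutoff", {
  m <- data.frame(miR = c("a", "b", "c"), degree = c(5, 4, 1))
  hubs <- select_degree_hubs(m, 0.8)
  expect_equal(hubs$cutoff, 4.0)
  expect_equal(hubs$hubs$miR, "a")   # 4 is not > 4
  single <- select_degree_hubs(data.frame(miR = "x", degree = 3), 0.8)
  expect_equal(single$hubs$miR, "x")
})

test_that("planted correlation blocks surface as top degree hubs", {
  sim <- generate_expression(sim_config(n_probes = 120, n_de = 0,
                                        block_sizes = 20, block_rho = 0.95,
                                        seed = 2))
  g <- threshold_edges(pearson_matrix(sim$dataset), 0.9)
  m <- node_metrics(g)
  blk <- names(sim$truth$block_assignments)
  top <- m$miR[order(-m$degree)][seq_len(min(20, nrow(m)))]
  expect_gte(mean(top %in% blk), 0.9)
})
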