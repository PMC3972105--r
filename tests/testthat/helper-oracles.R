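# Independent brute-force oracles used by the test suite. These
# deliberately avoid the code paths (and libraries) of the package
# implementation.

# Topological metrics from an adjacency matrix via Floyd-Warshall
# distances and combinatorial shortest-path counting.
oracle_graph_metrics <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  # sigma[s, t]: number of shortest s-t paths, filled in order of distance
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      preds <- which(adj[, t] > 0 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  betweenness <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(d[s, t])) next
      if (d[s, v] + d[v, t] == d[s, t])
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    betweenness[v] <- acc
  }
  ecc <- vapply(seq_len(n), function(v) {
    fin <- d[v, -v][is.finite(d[v, -v])]
    if (!length(fin)) 0 else max(fin)
  }, numeric(1))
  cc <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(adj[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, numeric(1))
  list(degree = rowSums(adj > 0), betweenness = betweenness,
       eccentricity = ecc, clustering_coefficient = cc)
}

# Exhaustive hypergeometric upper tail P(X >= k): enumerate all draws of
# size n from a universe of size N containing K marked items.
oracle_hyper_upper <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(cols) sum(cols %in% marked))
  mean(hits >= k)
}

# UPGMA merge heights recomputed from scratch: inter-cluster distance is
# the mean over all cross leaf pairs of the ORIGINAL distance matrix
# (no Lance-Williams recursion).
oracle_upgma_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      cd <- mean(d[clusters[[i]], clusters[[j]]])
      if (cd < best[1]) best <- c(cd, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Adjacency matrix of an Erdos-Renyi graph, for oracle comparisons.
random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  adj
}

graph_from_adjacency <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  structure(list(graph = g, r_min = NA, absolute = FALSE),
            class = "coexpression_graph")
}
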