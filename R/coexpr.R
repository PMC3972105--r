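#' Pairwise Pearson correlation of miR expression profiles
#'
#' Correlations are computed across all samples pooled (disease and
#' control together), with pairwise-complete observations when values
#' are missing. Zero-variance miRs have undefined correlations (`NA`)
#' against every partner and are excluded from edge building, with a
#' warning.
#'
#' @param dataset a [mir_expression] object, usually restricted to the
#'   DE miRs.
#' @param mirs optional character vector restricting the rows used.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(dataset, mirs = NULL) {
  stopifnot(inherits(dataset, "mir_expression"))
  values <- dataset$values
  if (!is.null(mirs)) {
    mirs <- canonicalize_mir(mirs)
    missing <- setdiff(mirs, rownames(values))
    if (length(missing))
      stop("miR(s) not in dataset: ", paste(missing, collapse = ", "),
           call. = FALSE)
    values <- values[mirs, , drop = FALSE]
  }
  sds <- apply(values, 1, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning(sum(sds == 0, na.rm = TRUE),
            " zero-variance miR(s): correlations undefined")
  r <- suppressWarnings(
    stats::cor(t(values), use = "pairwise.complete.obs", method = "pearson"))
  diag(r) <- 1
  r
}

#' Threshold a correlation matrix into a co-expression graph
#'
#' Links two miRs when their Pearson correlation strictly exceeds
#' `r_min` (signed by default: strong negative correlations do not form
#' edges; set `absolute = TRUE` to use `|r|`). Isolated miRs are
#' dropped unless `keep_isolated = TRUE`.
#'
#' @param corr symmetric correlation matrix (from [pearson_matrix]).
#' @param r_min strict lower bound for an edge (default 0.9).
#' @param absolute threshold on `|r|` instead of signed `r`.
#' @param keep_isolated retain nodes with no edge.
#' @return object of class `coexpression_graph` wrapping an undirected
#'   igraph with edge attribute `r`.
#' @export
threshold_edges <- function(corr, r_min = 0.9, absolute = FALSE,
                            keep_isolated = FALSE) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr)), na.rm = TRUE) > 1e-8)
    stop("correlation matrix must be symmetric", call. = FALSE)
  v <- corr
  if (absolute) v <- abs(v)
  v[is.na(v)] <- -Inf
  idx <- which(upper.tri(v) & v > r_min, arr.ind = TRUE)
  edges <- data.frame(from = rownames(corr)[idx[, 1]],
                      to = colnames(corr)[idx[, 2]],
                      r = corr[idx], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = rownames(corr), stringsAsFactors = FALSE))
  if (!keep_isolated)
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  structure(list(graph = g, r_min = r_min, absolute = absolute),
            class = "coexpression_graph")
}

#' @export
print.coexpression_graph <- function(x, ...) {
  cat(sprintf("co-expression graph: %d miRs, %d edges (r %s %g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (x$absolute) "|r| >" else ">", x$r_min))
  invisible(x)
}

#' @export
as_igraph.coexpression_graph <- function(network) {
  g <- network$graph
  igraph::E(g)$interaction <- "coexpressed"
  m <- node_metrics(network)
  igraph::V(g)$degree <- m$degree
  igraph::V(g)$betweenness <- m$betweenness
  igraph::V(g)$eccentricity <- m$eccentricity
  igraph::V(g)$clustering_coefficient <- m$clustering_coefficient
  g
}

#' Topological node metrics of a co-expression graph
#'
#' Computes, per node: degree (incident edge count); betweenness
#' centrality, unnormalized, summed over unordered node pairs with
#' endpoints excluded and unreachable pairs skipped; eccentricity, the
#' maximum finite shortest-path length from the node (0 for isolated
#' nodes); and the local clustering coefficient
#' `C = 2 e / (k (k - 1))` with `e` the number of edges among the
#' node's `k` neighbors, defined as 0 when `k < 2`.
#'
#' @param graph a `coexpression_graph` (or a bare undirected igraph).
#' @return data.frame with columns `miR`, `degree`, `betweenness`,
#'   `eccentricity`, `clustering_coefficient`.
#' @export
node_metrics <- function(graph) {
  g <- if (inherits(graph, "coexpression_graph")) graph$graph else graph
  stopifnot(igraph::is_igraph(g), !igraph::is_directed(g))
  data.frame(
    miR = igraph::V(g)$name,
    degree = unname(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                             weights = NA)),
    eccentricity = unname(igraph::eccentricity(g, mode = "all")),
    clustering_coefficient = igraph::transitivity(g, type = "localundirected",
                                                  isolates = "zero"),
    stringsAsFactors = FALSE)
}

#' Summary node statistics
#'
#' Average, standard deviation (population form, dividing by N),
#' minimum and maximum of each topological metric over all nodes.
#'
#' @param graph a `coexpression_graph` or its [node_metrics] table.
#' @return data.frame with rows per metric and columns `avg`, `sd`,
#'   `min`, `max`.
#' @export
summarize_nodes <- function(graph) {
  m <- if (is.data.frame(graph)) graph else node_metrics(graph)
  if (nrow(m) == 0) stop("empty graph", call. = FALSE)
  metrics <- c("degree", "betweenness", "eccentricity",
               "clustering_coefficient")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- t(vapply(metrics, function(k)
    c(avg = mean(m[[k]]), sd = pop_sd(m[[k]]), min = min(m[[k]]),
      max = max(m[[k]])), numeric(4)))
  as.data.frame(out)
}

#' Degree hubs of a co-expression graph
#'
#' Ranks nodes by degree and keeps those whose degree strictly exceeds
#' `fraction` times the maximum degree (default cutoff: 80% of the
#' maximum).
#'
#' @param graph a `coexpression_graph` or [node_metrics] table.
#' @param fraction fraction of the maximum degree (default 0.8).
#' @return list with `hubs` (data.frame `miR`, `degree`, sorted by
#'   degree descending then name) and `cutoff`.
#' @export
select_degree_hubs <- function(graph, fraction = 0.8) {
  m <- if (is.data.frame(graph)) graph else node_metrics(graph)
  if (nrow(m) == 0) stop("graph has no nodes", call. = FALSE)
  cutoff <- fraction * max(m$degree)
  hubs <- m[m$degree > cutoff, c("miR", "degree"), drop = FALSE]
  hubs <- hubs[order(-hubs$degree, hubs$miR), , drop = FALSE]
  rownames(hubs) <- NULL
  list(hubs = hubs, cutoff = cutoff)
}
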