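#' Intermediate regulation score
#'
#' A miR sitting in the middle layer of a TF -> miR -> mRNA tripartite
#' network receives signals from `m` transcription factors and relays
#' them to `n` target mRNAs, so the amount of regulatory information
#' passing through it is `m * n`. miRs with large IR are bottleneck
#' (hub) candidates.
#'
#' @param m in-degree: number of distinct TFs regulating the miR.
#' @param n out-degree: number of (top-k filtered) target genes.
#' @return `m * n`, vectorized.
#' @examples
#' ir_score(9, 10)   # 90
#' ir_score(13, 10)  # 130
#' @export
ir_score <- function(m, n) {
  stopifnot(all(m >= 0), all(n >= 0))
  m * n
}

#' Build a tripartite TF -> miR -> mRNA regulatory network
#'
#' Restricts the TF table and the filtered target table to a miR
#' subset (typically the miRs associated with the top enriched terms),
#' collapses duplicate TF -> miR records to single edges, and computes
#' each miR's in-degree `m`, out-degree `n` and intermediate regulation
#' `ir = m * n`. miRs with no known TF are retained with `m = 0`.
#' Layer purity is enforced: a name appearing in more than one of the
#' TF / miR / gene layers is an error.
#'
#' @param tf_table data.frame with columns `TF`, `miR` (and optionally
#'   `effect`, carried as an edge attribute).
#' @param targets data.frame with columns `miR`, `gene` — already
#'   consensus-, score- and top-k-filtered.
#' @param mir_subset character vector of miRs to include.
#' @return object of class `tripartite_network`: list with `tfs`,
#'   `mirs`, `genes`, `tf_edges`, `target_edges` and `mir_stats`
#'   (columns `miR`, `m`, `n`, `ir`).
#' @export
build_tripartite <- function(tf_table, targets, mir_subset) {
  mir_subset <- sort(unique(canonicalize_mir(mir_subset)))
  tf_table$miR <- canonicalize_mir(tf_table$miR)
  targets$miR <- canonicalize_mir(targets$miR)
  tf_edges <- unique(tf_table[tf_table$miR %in% mir_subset,
                              intersect(c("TF", "miR", "effect"),
                                        names(tf_table)), drop = FALSE])
  tf_edges <- tf_edges[!duplicated(tf_edges[c("TF", "miR")]), , drop = FALSE]
  target_edges <- targets[targets$miR %in% mir_subset,
                          intersect(c("miR", "gene", "score"), names(targets)),
                          drop = FALSE]
  tfs <- sort(unique(tf_edges$TF))
  genes <- sort(unique(target_edges$gene))
  overlap <- c(intersect(tfs, mir_subset), intersect(genes, mir_subset),
               intersect(tfs, genes))
  if (length(overlap))
    stop("layer violation: name(s) in two layers: ",
         paste(unique(overlap), collapse = ", "), call. = FALSE)
  m <- table(factor(tf_edges$miR, levels = mir_subset))
  n <- table(factor(target_edges$miR, levels = mir_subset))
  stats <- data.frame(miR = mir_subset, m = as.integer(m),
                      n = as.integer(n), stringsAsFactors = FALSE)
  stats$ir <- ir_score(stats$m, stats$n)
  structure(list(tfs = tfs, mirs = mir_subset, genes = genes,
                 tf_edges = tf_edges, target_edges = target_edges,
                 mir_stats = stats),
            class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat(sprintf("tripartite network: %d TFs -> %d miRs -> %d genes (%d + %d edges)\n",
              length(x$tfs), length(x$mirs), length(x$genes),
              nrow(x$tf_edges), nrow(x$target_edges)))
  invisible(x)
}

#' @export
as_igraph.tripartite_network <- function(network) {
  e1 <- data.frame(from = network$tf_edges$TF, to = network$tf_edges$miR,
                   interaction = "regulates", stringsAsFactors = FALSE)
  e2 <- data.frame(from = network$target_edges$miR,
                   to = network$target_edges$gene,
                   interaction = "targets", stringsAsFactors = FALSE)
  nodes <- data.frame(
    name = c(network$tfs, network$mirs, network$genes),
    layer = rep(c("TF", "miR", "gene"),
                c(length(network$tfs), length(network$mirs),
                  length(network$genes))),
    stringsAsFactors = FALSE)
  nodes$ir <- network$mir_stats$ir[match(nodes$name, network$mir_stats$miR)]
  igraph::graph_from_data_frame(rbind(e1, e2), directed = TRUE,
                                vertices = nodes)
}

#' Select intermediate-regulation hub miRs
#'
#' Keeps the miRs whose IR score meets the threshold (inclusive,
#' default 70) and ranks them by IR descending, ties by name.
#'
#' @param network a [tripartite_network] (or a data.frame with columns
#'   `miR`, `m`, `n` from which `ir` is recomputed).
#' @param threshold inclusive IR cutoff.
#' @return object of class `hub_report`: list with `hubs` (data.frame
#'   `miR`, `m`, `n`, `ir`) and `threshold`.
#' @export
select_ir_hubs <- function(network, threshold = 70) {
  stats <- if (inherits(network, "tripartite_network"))
    network$mir_stats
  else
    network
  stopifnot(all(c("miR", "m", "n") %in% names(stats)))
  stats$ir <- ir_score(stats$m, stats$n)
  hubs <- stats[stats$ir >= threshold, , drop = FALSE]
  hubs <- hubs[order(-hubs$ir, hubs$miR), , drop = FALSE]
  rownames(hubs) <- NULL
  structure(list(hubs = hubs, threshold = threshold), class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("%d IR hub miR(s) at threshold >= %g\n", nrow(x$hubs),
              x$threshold))
  if (nrow(x$hubs)) print(x$hubs, row.names = FALSE)
  invisible(x)
}

#' Rank transcription factors by out-degree
#'
#' @param network a [tripartite_network].
#' @return data.frame (`TF`, `out_degree`) sorted by out-degree
#'   descending, ties by name.
#' @export
tf_outdegree_ranking <- function(network) {
  stopifnot(inherits(network, "tripartite_network"))
  deg <- table(network$tf_edges$TF)
  out <- data.frame(TF = names(deg), out_degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$out_degree, out$TF), , drop = FALSE]
  rownames(out) <- NULL
  out
}
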