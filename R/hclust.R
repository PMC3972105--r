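#' Correlation distance between two expression profiles
#'
#' `d = 1 - r` with `r` the (centered) Pearson sample correlation, so
#' perfectly correlated profiles are at distance 0 and perfectly
#' anticorrelated profiles at distance 2.
#'
#' @param x,y numeric vectors of equal length (at least 3) with nonzero
#'   variance.
#' @return a distance in \[0, 2\].
#' @examples
#' correlation_distance(1:5, 2 * (1:5) + 1)  # 0
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("profiles must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation distance undefined for zero-variance profile",
         call. = FALSE)
  1 - stats::cor(x, y)
}

#' Correlation-distance matrix of an expression dataset
#'
#' @param dataset a [mir_expression] object.
#' @param mirs optional row subset.
#' @return symmetric matrix of `1 - r` distances with zero diagonal.
#' @export
correlation_dist_matrix <- function(dataset, mirs = NULL) {
  r <- pearson_matrix(dataset, mirs)
  d <- 1 - r
  diag(d) <- 0
  d
}

#' Agglomerative clustering with unweighted average linkage (UPGMA)
#'
#' Iteratively merges the two closest clusters, where the distance
#' between clusters is the unweighted mean of all cross-pair leaf
#' distances. Ties at the minimum are broken deterministically toward
#' the lexicographically smallest pair of cluster identifiers (a
#' cluster is identified by its smallest leaf name). Exactly
#' `n - 1` merges are performed.
#'
#' @param dist_matrix square symmetric numeric matrix with zero
#'   diagonal; row names are the leaf labels.
#' @return object of class `mir_dendrogram`: list with `merge` (as in
#'   [stats::hclust]: negative entries are leaves, positive entries
#'   earlier merges), `height`, `labels`.
#' @export
average_linkage <- function(dist_matrix) {
  d <- as.matrix(dist_matrix)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric", call. = FALSE)
  n <- nrow(d)
  labels <- rownames(d) %||% paste0("leaf", seq_len(n))
  if (n < 2) stop("need at least 2 leaves", call. = FALSE)
  diag(d) <- Inf
  active <- seq_len(n)
  node <- -seq_len(n)          # hclust convention
  size <- rep(1L, n)
  rep_name <- labels           # smallest member name per cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    sub <- d[active, active, drop = FALSE]
    dmin <- min(sub)
    cand <- which(sub == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    reps <- cbind(rep_name[active[cand[, 1]]], rep_name[active[cand[, 2]]])
    key <- paste(pmin(reps[, 1], reps[, 2]), pmax(reps[, 1], reps[, 2]),
                 sep = "\r")
    pick <- cand[order(key)[1], ]
    i <- active[min(pick)]; j <- active[max(pick)]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- dmin
    # unweighted (UPGMA) update: size-weighted mean of the two old rows
    others <- setdiff(active, c(i, j))
    d[i, others] <- d[others, i] <-
      (size[i] * d[i, others] + size[j] * d[j, others]) / (size[i] + size[j])
    size[i] <- size[i] + size[j]
    rep_name[i] <- min(rep_name[i], rep_name[j])
    node[i] <- step
    active <- setdiff(active, j)
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "mir_dendrogram")
}

#' @export
print.mir_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves, merge heights %.3g .. %.3g\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges. Cluster ids are assigned by
#' decreasing cluster size, ties by smallest member name, so the
#' labelling is deterministic.
#'
#' @param dendrogram a `mir_dendrogram` from [average_linkage].
#' @param k number of clusters, between 1 and the number of leaves.
#' @return named integer vector mapping each leaf to its cluster id,
#'   with an attribute `sizes` (cluster sizes in id order).
#' @export
cut_clusters <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "mir_dendrogram"))
  n <- length(dendrogram$labels)
  if (k < 1 || k > n) stop("k must be between 1 and ", n, call. = FALSE)
  members <- as.list(-seq_len(n))       # keyed by -leaf / +merge-step
  names(members) <- as.character(-seq_len(n))
  for (step in seq_len(n - k)) {
    pair <- dendrogram$merge[step, ]
    members[[as.character(step)]] <-
      c(members[[as.character(pair[1])]], members[[as.character(pair[2])]])
    members[[as.character(pair[1])]] <- NULL
    members[[as.character(pair[2])]] <- NULL
  }
  clusters <- lapply(members, function(m) sort(dendrogram$labels[-m]))
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, `[`, character(1), 1))
  clusters <- clusters[ord]
  out <- integer(n)
  names(out) <- dendrogram$labels
  for (id in seq_along(clusters)) out[clusters[[id]]] <- id
  attr(out, "sizes") <- vapply(clusters, length, integer(1))
  out
}
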