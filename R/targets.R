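#' Consensus filtering of predicted miR targets
#'
#' Keeps (miR, gene) pairs predicted by at least `required_predictors`
#' distinct predictors — the offline analogue of intersecting target
#' lists from several prediction servers. The record retained for a
#' consensus pair carries the pair's consensus score: the score from
#' `score_predictor` when that predictor lists the pair, otherwise the
#' maximum score across predictors. Other predictors only vote
#' membership.
#'
#' @param table data.frame with columns `miR`, `gene`, `predictor`,
#'   `score`.
#' @param required_predictors minimum number of distinct predictors.
#' @param score_predictor predictor whose score is authoritative
#'   (default `"diana"`, the miTG-style score).
#' @return data.frame with columns `miR`, `gene`, `score`,
#'   `n_predictors`.
#' @export
consensus_targets <- function(table, required_predictors = 3,
                              score_predictor = "diana") {
  stopifnot(all(c("miR", "gene", "predictor", "score") %in% names(table)))
  n_distinct <- length(unique(table$predictor))
  if (nrow(table) > 0 && required_predictors > n_distinct)
    stop("required_predictors (", required_predictors,
         ") exceeds distinct predictors in table (", n_distinct, ")",
         call. = FALSE)
  if (nrow(table) == 0)
    return(data.frame(miR = character(), gene = character(),
                      score = numeric(), n_predictors = integer()))
  table$miR <- canonicalize_mir(table$miR)
  key <- paste(table$miR, table$gene, sep = "\r")
  votes <- tapply(table$predictor, key, function(p) length(unique(p)))
  keep_keys <- names(votes)[votes >= required_predictors]
  out <- lapply(keep_keys, function(k) {
    rec <- table[key == k, ]
    sc <- rec$score[rec$predictor == score_predictor]
    if (!length(sc)) sc <- max(rec$score)
    data.frame(miR = rec$miR[1], gene = rec$gene[1], score = sc[1],
               n_predictors = length(unique(rec$predictor)))
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(miR = character(), gene = character(),
                      score = numeric(), n_predictors = integer())
  out[order(out$miR, out$gene), , drop = FALSE]
}

#' Score filtering of consensus targets
#'
#' Retains targets whose consensus (miTG-style) score is at least
#' `min_score`; the boundary is inclusive, matching the convention that
#' a score equal to the reliability threshold is still high-confidence.
#'
#' @param table data.frame with a `score` column (usually the output of
#'   [consensus_targets]).
#' @param min_score inclusive lower bound (default 20).
#' @return the filtered data.frame.
#' @export
filter_by_score <- function(table, min_score = 20) {
  stopifnot("score" %in% names(table))
  table[table$score >= min_score, , drop = FALSE]
}

#' Per-miR top-k targets
#'
#' Keeps, for each miR, the `k` highest-scoring target records (all of
#' them when fewer than `k` exist). Score ties at the k-th place are
#' broken by gene name ascending, so the selection is deterministic.
#'
#' @inheritParams filter_by_score
#' @param k per-miR cap (default 10).
#' @return the filtered data.frame.
#' @export
top_k_targets <- function(table, k = 10) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  stopifnot(all(c("miR", "gene", "score") %in% names(table)))
  if (nrow(table) == 0) return(table)
  keep <- unlist(lapply(split(seq_len(nrow(table)), table$miR), function(idx) {
    rec <- table[idx, ]
    idx[order(-rec$score, rec$gene)][seq_len(min(k, length(idx)))]
  }), use.names = FALSE)
  out <- table[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unique genes targeted by a miR set
#'
#' @param mirs character vector of miR names.
#' @param table filtered target data.frame with columns `miR`, `gene`.
#' @return sorted character vector: the union of genes targeted by
#'   `mirs`.
#' @export
unique_target_genes <- function(mirs, table) {
  mirs <- canonicalize_mir(mirs)
  sort(unique(table$gene[canonicalize_mir(table$miR) %in% mirs]))
}
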