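# Small fixture builders shared across test files.

tiny_dataset <- function(values, n_disease, n_control) {
  values <- as.matrix(values)
  colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("hsa-mir-t", seq_len(nrow(values)))
  mir_expression(values, rep(c("disease", "control"),
                             c(n_disease, n_control)))
}

# target table where each record of `pairs` (miR, gene, score) appears
# under the given predictors
target_fixture <- function(pairs, predictors = list()) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    preds <- if (i <= length(predictors)) predictors[[i]] else NULL
    preds <- preds %||% c("diana", "miranda", "targetscan")
    data.frame(miR = pairs$miR[i], gene = pairs$gene[i], predictor = preds,
               score = pairs$score[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
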