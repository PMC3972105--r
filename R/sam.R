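#' Parameters for SAM differential expression
#'
#' @param fdr_target target false discovery rate for the call set, as a
#'   fraction (default 0.003, i.e. 0.3%).
#' @param n_permutations number of group-label permutations for the null
#'   distribution. When this is at least the number of distinct label
#'   assignments, all assignments are enumerated exhaustively and the
#'   result no longer depends on the seed.
#' @param seed integer seed for the permutation stream.
#' @param s0_percentiles candidate grid for the exchangeability constant
#'   s0, expressed as fractions of the per-miR standard-error
#'   distribution.
#' @return a list of class `sam_params`.
#' @export
sam_params <- function(fdr_target = 0.003, n_permutations = 1000, seed = 1,
                       s0_percentiles = seq(0, 1, by = 0.05)) {
  if (!(fdr_target > 0 && fdr_target < 1))
    stop_config("fdr_target", "must lie in (0, 1)")
  if (n_permutations < 1)
    stop_config("n_permutations", "must be at least 1")
  structure(list(fdr_target = fdr_target,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 s0_percentiles = s0_percentiles),
            class = "sam_params")
}

# Per-miR group summaries; probes with fewer than 2 usable values in
# either group are flagged unusable.
sam_row_stats <- function(dataset) {
  disease <- dataset$values[, dataset$groups == "disease", drop = FALSE]
  control <- dataset$values[, dataset$groups == "control", drop = FALSE]
  n1 <- rowSums(!is.na(disease))
  n2 <- rowSums(!is.na(control))
  m1 <- rowMeans(disease, na.rm = TRUE)
  m2 <- rowMeans(control, na.rm = TRUE)
  ss1 <- rowSums((disease - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((control - m2)^2, na.rm = TRUE)
  usable <- n1 >= 2 & n2 >= 2
  r <- m1 - m2
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  r[!usable] <- NA_real_
  s[!usable] <- NA_real_
  data.frame(miR = rownames(dataset$values), r = r, s = s, usable = usable,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' SAM relative-difference statistic
#'
#' Computes, per miR, the two-class unpaired SAM statistic
#' `d = r / (s + s0)` where `r` is the disease-minus-control group mean
#' difference and `s` the pooled standard error
#' `sqrt((1/n1 + 1/n2) * SS_within / (n1 + n2 - 2))`. miRs with fewer
#' than two usable values in either group are flagged unusable and
#' excluded from calling.
#'
#' @param dataset a [mir_expression] object.
#' @param s0 non-negative exchangeability constant added to the
#'   denominator (see [choose_s0]).
#' @return data.frame with columns `miR`, `d`, `r`, `s`, `usable`.
#' @examples
#' m <- rbind("hsa-mir-1" = c(3, 4, 5, 1, 2, 3))
#' colnames(m) <- paste0("s", 1:6)
#' ds <- mir_expression(m, rep(c("disease", "control"), each = 3))
#' sam_statistic(ds, s0 = 0)  # r = 2, s = sqrt(2/3)
#' @export
sam_statistic <- function(dataset, s0 = 0) {
  stopifnot(inherits(dataset, "mir_expression"), s0 >= 0)
  st <- sam_row_stats(dataset)
  st$d <- st$r / (st$s + s0)
  # equal groups give r = 0 hence d = 0 even when s + s0 = 0
  st$d[st$usable & st$r == 0] <- 0
  st[c("miR", "d", "r", "s", "usable")]
}

#' Choose the SAM exchangeability constant s0
#'
#' Evaluates candidate values of s0 at percentiles of the per-miR
#' standard-error distribution and returns the candidate minimizing the
#' coefficient of variation of the d statistic across the range of s.
#' Following the original procedure, miRs are split into up to 100
#' windows by quantiles of s, the median absolute deviation of d is
#' taken within each window, and the coefficient of variation of those
#' window MADs is the objective. Ties are broken toward the smallest
#' candidate. With fewer than 20 usable miRs the median of s is returned
#' with a warning.
#'
#' @param dataset a [mir_expression] object.
#' @param s0_percentiles candidate percentiles (fractions in \[0, 1\]).
#' @return a single non-negative s0 value.
#' @export
choose_s0 <- function(dataset, s0_percentiles = seq(0, 1, by = 0.05)) {
  st <- sam_row_stats(dataset)
  st <- st[st$usable, ]
  if (nrow(st) < 20) {
    warning("fewer than 20 usable miRs; s0 set to median(s)")
    return(stats::median(st$s))
  }
  candidates <- unname(stats::quantile(st$s, probs = s0_percentiles))
  n_windows <- min(100L, max(1L, floor(nrow(st) / 2)))
  breaks <- unique(stats::quantile(st$s, probs = seq(0, 1, length.out = n_windows + 1)))
  win <- if (length(breaks) > 2)
    cut(st$s, breaks = breaks, include.lowest = TRUE)
  else
    factor(rep(1L, nrow(st)))
  cv_of <- function(s0) {
    d <- st$r / (st$s + s0)
    mads <- tapply(d, win, stats::mad)
    mads <- mads[!is.na(mads)]
    m <- mean(mads)
    if (!is.finite(m) || m == 0) return(0)
    stats::sd(mads) / m
  }
  cvs <- vapply(candidates, cv_of, numeric(1))
  candidates[which.min(cvs)]  # which.min takes the first, i.e. smallest, tie
}

# All or sampled assignments of n1 "disease" labels among n samples,
# as a list of disease-column index vectors.
permutation_plan <- function(n, n1, n_permutations, seed) {
  total <- choose(n, n1)
  if (n_permutations >= total) {
    plan <- utils::combn(n, n1, simplify = FALSE)
    attr(plan, "exhaustive") <- TRUE
    return(plan)
  }
  plan <- withr::with_seed(seed,
    replicate(n_permutations, sort(sample.int(n, n1)), simplify = FALSE))
  attr(plan, "exhaustive") <- FALSE
  plan
}

# d statistics under one relabelling, reusing the dataset matrix.
sam_d_permuted <- function(values, disease_idx, s0) {
  disease <- values[, disease_idx, drop = FALSE]
  control <- values[, -disease_idx, drop = FALSE]
  n1 <- rowSums(!is.na(disease))
  n2 <- rowSums(!is.na(control))
  m1 <- rowMeans(disease, na.rm = TRUE)
  m2 <- rowMeans(control, na.rm = TRUE)
  ss1 <- rowSums((disease - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((control - m2)^2, na.rm = TRUE)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  d <- (m1 - m2) / (s + s0)
  d[m1 == m2] <- 0
  d
}

#' SAM with permutation-estimated FDR
#'
#' Runs the full two-class SAM procedure: fits s0, computes observed d
#' statistics, builds a null distribution of d by permuting the group
#' labels (exhaustively when the number of distinct label assignments
#' does not exceed `n_permutations`), and tunes the symmetric threshold
#' delta on `d_(i) - dbar_(i)` (observed minus expected order statistic)
#' to the largest call set whose estimated FDR does not exceed
#' `fdr_target`. The FDR at a cut is the median over permutations of the
#' number of permuted d values beyond the cut, divided by the observed
#' number called. Probes with more than 20% missing values are dropped
#' with a warning before fitting.
#'
#' @param dataset a [mir_expression] object.
#' @param params a [sam_params] object.
#' @return an object of class `sam_result`: a list with `table` (columns
#'   `miR`, `d`, `r`, `s`, `q`, `called`, `direction`), `s0`, `delta`,
#'   `n_called`, `fdr_target`, `n_permutations`, `exhaustive`.
#' @export
sam_fdr <- function(dataset, params = sam_params()) {
  stopifnot(inherits(dataset, "mir_expression"))
  frac_missing <- rowMeans(is.na(dataset$values))
  if (any(frac_missing > 0.2)) {
    warning(sprintf("%d probe(s) with >20%% missing values excluded from SAM",
                    sum(frac_missing > 0.2)))
    dataset$values <- dataset$values[frac_missing <= 0.2, , drop = FALSE]
  }
  s0 <- choose_s0(dataset, params$s0_percentiles)
  st <- sam_statistic(dataset, s0 = s0)
  use <- st$usable & is.finite(st$d)
  d_obs <- st$d[use]
  p <- length(d_obs)
  if (p == 0) stop("no usable miRs for SAM", call. = FALSE)

  n <- ncol(dataset$values)
  n1 <- sum(dataset$groups == "disease")
  plan <- permutation_plan(n, n1, params$n_permutations, params$seed)
  values <- dataset$values[st$usable & is.finite(st$d), , drop = FALSE]
  perm_d <- matrix(vapply(plan, function(idx) sam_d_permuted(values, idx, s0),
                          numeric(p)), nrow = p)   # p x B
  B <- ncol(perm_d)

  ord <- order(d_obs)
  d_sorted <- d_obs[ord]
  dbar <- rowMeans(matrix(apply(perm_d, 2, sort), nrow = p))
  diff <- d_sorted - dbar

  cuts_for_delta <- function(delta) {
    up <- d_sorted[diff >= delta & d_sorted > 0]
    dn <- d_sorted[diff <= -delta & d_sorted < 0]
    c(if (length(up)) min(up) else Inf,
      if (length(dn)) max(dn) else -Inf)
  }
  eval_delta <- function(delta) {
    cuts <- cuts_for_delta(delta)
    called <- d_obs >= cuts[1] | d_obs <= cuts[2]
    n_called <- sum(called)
    if (n_called == 0) return(list(fdr = 0, called = called, n = 0))
    null_counts <- colSums(perm_d >= cuts[1]) + colSums(perm_d <= cuts[2])
    list(fdr = stats::median(null_counts) / n_called, called = called,
         n = n_called)
  }

  deltas <- sort(unique(abs(diff)))
  deltas <- deltas[deltas > 0]
  q <- rep(Inf, p)
  best <- NULL
  best_delta <- NA_real_
  for (delta in deltas) {
    ev <- eval_delta(delta)
    q[ev$called] <- pmin(q[ev$called], ev$fdr)
    if (ev$fdr <= params$fdr_target &&
        (is.null(best) || ev$n > best$n)) {
      best <- ev
      best_delta <- delta
    }
  }
  called <- if (is.null(best)) rep(FALSE, p) else best$called
  if (is.null(best))
    message("no delta achieves the FDR target; empty call set")
  q[!is.finite(q)] <- 1
  q <- pmin(q, 1)

  table <- st[c("miR", "d", "r", "s")]
  table$q <- NA_real_
  table$q[use] <- q
  table$called <- FALSE
  table$called[use] <- called
  table$direction <- ifelse(table$d > 0, "up",
                            ifelse(table$d < 0, "down", "flat"))
  table$direction[!use] <- NA_character_
  structure(list(table = table, s0 = s0, delta = best_delta,
                 n_called = sum(called), fdr_target = params$fdr_target,
                 n_permutations = B,
                 exhaustive = isTRUE(attr(plan, "exhaustive"))),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("SAM: %d miRs, s0 = %.4g, delta = %.4g, %d called at FDR <= %g%s\n",
              nrow(x$table), x$s0, x$delta, x$n_called, x$fdr_target,
              if (x$exhaustive) " (exhaustive permutations)" else ""))
  invisible(x)
}

#' Differentially expressed miRs from a SAM result
#'
#' @param result a `sam_result` from [sam_fdr].
#' @return character vector of canonical miR names, sorted by `|d|`
#'   descending (ties by name).
#' @export
select_de <- function(result) {
  stopifnot(inherits(result, "sam_result"))
  tab <- result$table[result$table$called, ]
  tab <- tab[order(-abs(tab$d), tab$miR), ]
  canonicalize_mir(tab$miR)
}
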