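#' Overlap of the DE set with a curated known-disease list
#'
#' Tests whether the differentially expressed miRs overlap a curated
#' list of disease-associated miRs more than expected by chance, using
#' the hypergeometric upper tail: with a background universe of size
#' `background` containing `|known|` known miRs, and `|de|` draws,
#' `p = P(X >= n_overlap)`. Known-list entries absent from the assayed
#' universe still count toward `n_known` but cannot contribute overlap.
#'
#' @param de character vector of DE miR names.
#' @param known character vector of known disease-miR names.
#' @param background size of the miR universe (e.g. probes assayed).
#' @return a list of class `overlap_result` with `n_de`, `n_known`,
#'   `n_overlap`, `background`, `p_value`, `group1` (DE and known) and
#'   `group2` (DE only).
#' @examples
#' overlap_significance(paste0("mir-", 1:5), paste0("mir-", 4:9), 100)
#' @export
overlap_significance <- function(de, known, background) {
  de <- unique(canonicalize_mir(de))
  known <- unique(canonicalize_mir(known))
  union_size <- length(union(de, known))
  if (background < union_size)
    stop("background (", background, ") smaller than |de union known| (",
         union_size, ")", call. = FALSE)
  groups <- partition_groups(de, known)
  n_overlap <- length(groups$group1)
  # upper tail P(X >= n_overlap), X ~ Hypergeom(background, |known|, |de|)
  p <- stats::phyper(n_overlap - 1, length(known),
                     background - length(known), length(de),
                     lower.tail = FALSE)
  structure(list(n_de = length(de), n_known = length(known),
                 n_overlap = n_overlap, background = background,
                 p_value = p, group1 = groups$group1,
                 group2 = groups$group2),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d of %d DE miRs in known list of %d (background %d), p = %.3g\n",
    x$n_overlap, x$n_de, x$n_known, x$background, x$p_value))
  invisible(x)
}

#' Partition DE miRs by known-disease status
#'
#' Group 1 holds the DE miRs also present in the curated known list;
#' Group 2 holds the remaining DE miRs (candidate novel disease miRs).
#' The partition is exact and exhaustive; both groups are returned in
#' sorted order.
#'
#' @inheritParams overlap_significance
#' @return list with character vectors `group1` and `group2`.
#' @export
partition_groups <- function(de, known) {
  de <- unique(canonicalize_mir(de))
  known <- unique(canonicalize_mir(known))
  list(group1 = sort(intersect(de, known)),
       group2 = sort(setdiff(de, known)))
}
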