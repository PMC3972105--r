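#' Over-representation analysis against annotation sets
#'
#' Offline hypergeometric enrichment of a query gene set against GMT
#' annotation sets, replacing web-service over-representation tools.
#' For a term of size `K` (after intersecting with the background), a
#' query of size `n` and `k` query genes in the term,
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` and `N` the
#' background size. Terms with `k = 0` are suppressed. A
#' Benjamini-Hochberg adjusted p-value is appended.
#'
#' @param query character vector of query genes; must lie inside
#'   `background`.
#' @param sets annotation sets as returned by [read_gmt].
#' @param background character vector: the gene universe.
#' @return data.frame with columns `term`, `description`, `k`, `K`,
#'   `n`, `N`, `p_value`, `adjusted_p`, sorted by `p_value` ascending
#'   (ties by term).
#' @export
enrich <- function(query, sets, background) {
  query <- unique(query)
  background <- unique(background)
  outside <- setdiff(query, background)
  if (length(outside))
    stop("query gene(s) outside background: ",
         paste(utils::head(outside, 10), collapse = ", "), call. = FALSE)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]]$genes, background)
    K <- length(members)
    k <- length(intersect(query, members))
    if (k == 0) return(NULL)
    data.frame(term = id, description = sets[[id]]$description %||% "",
               k = k, K = K, n = n, N = N,
               p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric())
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Significant terms from an enrichment result
#'
#' Default is the unadjusted p-value at `alpha = 0.05`;
#' `use_adjusted = TRUE` switches to the Benjamini-Hochberg column.
#'
#' @param rows enrichment data.frame from [enrich].
#' @param alpha significance cutoff (strict `<`).
#' @param use_adjusted filter on `adjusted_p` instead of `p_value`.
#' @return the filtered rows, original order preserved.
#' @export
significant_terms <- function(rows, alpha = 0.05, use_adjusted = FALSE) {
  p <- if (use_adjusted) rows$adjusted_p else rows$p_value
  rows[p < alpha, , drop = FALSE]
}

#' miRs associated with the most enriched terms
#'
#' Selects the miRs whose filtered target genes intersect the union of
#' member genes of the `top_n` most significant terms — the rule used
#' to restrict a group's miRs to those acting in its top enriched
#' biological processes before building the regulatory network.
#'
#' @param rows enrichment data.frame sorted by p (as from [enrich]).
#' @param sets the annotation sets the rows were computed from.
#' @param mir_to_genes named list mapping each miR to its (filtered)
#'   target genes, or a target data.frame with columns `miR`, `gene`.
#' @param top_n number of top terms to use (default 20).
#' @return sorted character vector of selected miR names.
#' @export
mirs_for_top_terms <- function(rows, sets, mir_to_genes, top_n = 20) {
  if (top_n <= 0 || nrow(rows) == 0) return(character())
  terms <- utils::head(rows$term, top_n)
  pool <- unique(unlist(lapply(sets[terms], `[[`, "genes")))
  if (is.data.frame(mir_to_genes))
    mir_to_genes <- split(mir_to_genes$gene, canonicalize_mir(mir_to_genes$miR))
  hit <- vapply(mir_to_genes,
                function(g) length(intersect(g, pool)) > 0, logical(1))
  sort(canonicalize_mir(names(mir_to_genes)[hit]))
}
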