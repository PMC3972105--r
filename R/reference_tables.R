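#' Reference in-/out-degree tables for PD regulatory hub miRs
#'
#' Curated (miR, in-degree, out-degree) values for the Group 1
#' (known PD-associated) and Group 2 (candidate novel) tripartite
#' regulatory networks, bundled as worked reference input for the
#' intermediate-regulation scoring rule: `ir_score` applied to these
#' rows reproduces the published IR hub rankings (top IR 90 for
#' Group 1, 130 for Group 2; 5 and 9 hubs at threshold 70).
#'
#' @param group `"group1"` or `"group2"`.
#' @return data.frame with columns `miR`, `m` (in-degree), `n`
#'   (out-degree).
#' @examples
#' tab <- ir_reference_degrees("group1")
#' max(ir_score(tab$m, tab$n))  # 90
#' @export
ir_reference_degrees <- function(group = c("group1", "group2")) {
  group <- match.arg(group)
  path <- system.file("extdata", sprintf("ir_reference_%s.tsv", group),
                      package = "hubmir", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
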