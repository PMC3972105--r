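#' Read and write GMT annotation sets
#'
#' Standard GMT: one term per line, tab-separated fields
#' `term<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within
#' a line are collapsed with a warning (sets have set semantics); lines
#' with fewer than three fields are a parse error reported with their
#' line number. Empty sets are invalid and never written.
#'
#' @param path file path.
#' @return `read_gmt` returns a named list of annotation sets; each
#'   element has `description` and `genes` (character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i),
           call. = FALSE)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): duplicate genes collapsed",
                      i, fields[[1]]))
      genes <- unique(genes)
    }
    sets[[fields[[1]]]] <- list(description = fields[[2]], genes = genes)
  }
  sets
}

#' @rdname read_gmt
#' @param sets a named list as returned by `read_gmt`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    s <- sets[[id]]
    if (!length(s$genes)) stop("empty annotation set: ", id, call. = FALSE)
    paste(c(id, s$description %||% "", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write edge tables
#'
#' Tab-separated, header required. The TF table has columns
#' `TF`, `miR`, `effect`; the target table has columns
#' `miR`, `gene`, `predictor`, `score`. miR names are canonicalized on
#' read.
#'
#' @param path file path.
#' @return a data.frame with the table's columns.
#' @export
read_tf_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("TF", "miR", "effect")
  if (!all(need %in% names(tab)))
    stop("TF table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  tab$miR <- canonicalize_mir(tab$miR)
  tab
}

#' @rdname read_tf_table
#' @export
read_target_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("miR", "gene", "predictor", "score")
  if (!all(need %in% names(tab)))
    stop("target table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab$miR <- canonicalize_mir(tab$miR)
  if (!is.numeric(tab$score) || any(!is.finite(tab$score)))
    stop("target scores must be finite numbers", call. = FALSE)
  if (anyDuplicated(tab[c("miR", "gene", "predictor")]))
    stop("duplicate (miR, gene, predictor) records in target table",
         call. = FALSE)
  tab
}

#' @rdname read_tf_table
#' @param table data.frame to write.
#' @export
write_edge_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a known disease-miR list
#'
#' One miR name per line; names are canonicalized and deduplicated.
#'
#' @param path file path.
#' @return character vector of canonical miR names.
#' @export
read_mir_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  unique(canonicalize_mir(x[nzchar(trimws(x))]))
}

#' @rdname read_mir_list
#' @param mirs character vector of miR names.
#' @export
write_mir_list <- function(mirs, path) {
  writeLines(canonicalize_mir(mirs), path)
  invisible(path)
}

#' Export a network for external visualization
#'
#' Writes either Cytoscape SIF (interaction labels `regulates` for
#' TF->miR edges, `targets` for miR->gene edges, `coexpressed` for
#' miR-miR edges) or GraphML carrying whatever node attributes are
#' present (layer, degree, IR, betweenness, eccentricity, clustering
#' coefficient).
#'
#' @param network a [tripartite_network] or [coexpression_graph].
#' @param path output file.
#' @param dialect `"SIF"` or `"GraphML"`.
#' @return the path, invisibly.
#' @export
write_network <- function(network, path, dialect = c("SIF", "GraphML")) {
  dialect <- match.arg(dialect)
  g <- as_igraph(network)
  if (dialect == "SIF") {
    el <- igraph::as_edgelist(g)
    writeLines(paste(el[, 1], igraph::E(g)$interaction, el[, 2], sep = "\t"),
               path)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a pipeline network to an igraph object
#'
#' @param network a [tripartite_network] or [coexpression_graph].
#' @return an igraph graph with an `interaction` edge attribute and the
#'   network's node attributes.
#' @export
as_igraph <- function(network) UseMethod("as_igraph")
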