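#' Two-group expression dataset
#'
#' Container for a probes x samples matrix of log2(Hy3/Hy5) ratios with a
#' per-sample group label. This is the common input of the differential
#' expression, co-expression and clustering stages.
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#'   Row names are miR names (canonicalized on construction), column
#'   names are sample identifiers. `NA` entries mark missing values.
#' @param groups character or factor of length `ncol(values)` with
#'   values `"disease"` or `"control"`, named by sample or in column
#'   order.
#' @return an object of class `mir_expression` with elements `values`
#'   and `groups`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("mir-", 1:3), paste0("s", 1:4)))
#' ds <- mir_expression(m, c("disease", "disease", "control", "control"))
#' ds
#' @export
mir_expression <- function(values, groups) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs probe row names and sample column names",
         call. = FALSE)
  rownames(values) <- canonicalize_mir(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe names: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  groups <- stats::setNames(as.character(groups), names(groups))
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("metadata missing sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    groups <- groups[colnames(values)]
  }
  if (length(groups) != ncol(values))
    stop("need one group label per sample", call. = FALSE)
  bad <- setdiff(unique(groups), c("disease", "control"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!all(c("disease", "control") %in% groups))
    stop("both 'disease' and 'control' groups must be non-empty", call. = FALSE)
  if (any(is.infinite(values)))
    stop("expression values must be finite or NA", call. = FALSE)
  structure(list(values = values,
                 groups = stats::setNames(factor(groups,
                                                 levels = c("disease", "control")),
                                          colnames(values))),
            class = "mir_expression")
}

#' @export
print.mir_expression <- function(x, ...) {
  cat(sprintf("mir_expression: %d probes x %d samples (%d disease, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "disease"), sum(x$groups == "control")))
  if (anyNA(x$values))
    cat(sprintf("  %d missing values\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.mir_expression <- function(x) dim(x$values)

#' Read / write a two-group expression dataset
#'
#' The matrix file is UTF-8 tab-separated with a header row of sample
#' names and a first column of probe names; cells are numeric or `NA`.
#' The metadata file is tab-separated with columns `sample` and `group`
#' (`disease`/`control`). Column order of the matrix is preserved.
#'
#' @param path path of the expression matrix TSV.
#' @param metadata_path path of the sample-metadata TSV.
#' @return `read_expression` returns a [mir_expression] object.
#' @export
read_expression <- function(path, metadata_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs a probe column plus samples",
                          call. = FALSE)
  probes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(mat), dim(mat)))) &
                   !is.na(mat) & mat != "NA", arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric cell at row %d, column %d of %s",
                   bad[1, 1], bad[1, 2] + 1L, path), call. = FALSE)
    mat <- array(suppressWarnings(as.numeric(mat)), dim(mat),
                 dimnames = dimnames(mat))
  }
  rownames(mat) <- probes
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(meta)))
    stop("metadata needs columns 'sample' and 'group'", call. = FALSE)
  mir_expression(mat, stats::setNames(meta$group, meta$sample))
}

#' @rdname read_expression
#' @param dataset a [mir_expression] object.
#' @export
write_expression <- function(dataset, path, metadata_path) {
  stopifnot(inherits(dataset, "mir_expression"))
  tab <- data.frame(miR = rownames(dataset$values), dataset$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = colnames(dataset$values),
                     group = as.character(dataset$groups))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, metadata_path))
}
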