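#' Canonicalize miR names
#'
#' Applies the shared naming rule used at every file boundary: trim
#' surrounding whitespace, lowercase, and prepend the `"hsa-"` species
#' prefix when absent. Overlap counting, partitioning and network joins
#' all key on the canonical form, so mixed-case or prefix-less inputs
#' (`"MiR-21"`, `"miR-9"`) compare equal to their canonical spelling.
#'
#' @param x character vector of miR names.
#' @return character vector of canonical names.
#' @examples
#' canonicalize_mir(c(" MiR-21", "hsa-let-7a", "miR-9 "))
#' @export
canonicalize_mir <- function(x) {
  x <- tolower(trimws(as.character(x)))
  missing_prefix <- !startsWith(x, "hsa-") & nzchar(x)
  x[missing_prefix] <- paste0("hsa-", x[missing_prefix])
  x
}

# Derive a reproducible 32-bit sub-seed for a named random stream, so that
# adding a generator never perturbs the draws of the others.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- utf8ToInt(stream)
  acc <- as.double(seed) %% 2147483647
  for (ch in h) acc <- (acc * 131 + ch) %% 2147483647
  as.integer(acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}
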