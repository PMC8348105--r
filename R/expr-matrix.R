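#' Expression matrix container
#'
#' A light wrapper around a genes x samples numeric matrix carrying a scale
#' flag, so that linear-intensity data cannot silently be fed to operations
#' that expect log2 values (or be log2-transformed twice).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Ids must be unique and non-empty.
#' @param scale Either `"log2"` or `"linear"`. Linear values must be >= 0.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `scale`.
#' @examples
#' m <- expr_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("g", 1:3), c("s1", "s2"))), scale = "linear")
#' dim(m)
#' @export
expr_matrix <- function(values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene row names and sample column names")
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g)) {
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing")
  }
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale expression values must be >= 0")
  }
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "expr_matrix: %d genes x %d samples (%s scale)\n",
    nrow(x$values), ncol(x$values), x$scale
  ))
  invisible(x)
}

#' Gene and sample identifiers of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of ids, in matrix order.
#' @export
gene_ids <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  rownames(m$values)
}

#' @rdname gene_ids
#' @export
sample_ids <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  colnames(m$values)
}

#' Restrict an expression matrix to a subset of samples or genes
#'
#' @param m An `expr_matrix`.
#' @param ids Character vector of sample (or gene) ids to keep; every id must
#'   be present. Output order follows `ids`.
#' @return An `expr_matrix` on the same scale.
#' @export
subset_samples <- function(m, ids) {
  stopifnot(inherits(m, "expr_matrix"))
  miss <- setdiff(ids, colnames(m$values))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  expr_matrix(m$values[, ids, drop = FALSE], scale = m$scale)
}

#' @rdname subset_samples
#' @export
subset_genes <- function(m, ids) {
  stopifnot(inherits(m, "expr_matrix"))
  miss <- setdiff(ids, rownames(m$values))
  if (length(miss)) stop("unknown gene id(s): ", paste(miss, collapse = ", "))
  expr_matrix(m$values[ids, , drop = FALSE], scale = m$scale)
}
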