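#' PCA on a variance-filtered expression matrix
#'
#' Samples are observations and genes variables; each gene is centered and
#' scaled to unit variance before the decomposition (via [stats::prcomp()]).
#' The result is deterministic up to component sign.
#'
#' @param filtered Log2-scale, variance-filtered `expr_matrix`; every gene
#'   must vary across samples.
#' @return A `cohort_pca`: list with `scores` (samples x components),
#'   `loadings` (genes x components), `var_explained` (fraction per
#'   component) and `sdev`.
#' @export
run_pca <- function(filtered) {
  stopifnot(inherits(filtered, "expr_matrix"))
  if (filtered$scale != "log2") stop("PCA expects log2-scale values")
  if (ncol(filtered$values) < 2) stop("PCA needs at least 2 samples")
  if (any(row_vars(filtered$values) == 0)) {
    stop("zero-variance gene(s) present: apply filter_by_variance() first")
  }
  p <- stats::prcomp(t(filtered$values), center = TRUE, scale. = TRUE)
  structure(
    list(
      scores = p$x,
      loadings = p$rotation,
      var_explained = p$sdev^2 / sum(p$sdev^2),
      sdev = p$sdev
    ),
    class = "cohort_pca"
  )
}

#' @export
print.cohort_pca <- function(x, ...) {
  ve <- x$var_explained
  k <- min(3, length(ve))
  cat(sprintf(
    "cohort_pca: %d samples, %d components; %s\n",
    nrow(x$scores), length(ve),
    paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * ve[seq_len(k)]), collapse = ", ")
  ))
  invisible(x)
}

resolve_components <- function(pca, components) {
  k <- ncol(pca$scores)
  if (is.null(components)) {
    return(seq_len(k))
  }
  if (any(components < 1 | components > k)) {
    stop("requested component(s) outside 1..", k)
  }
  as.integer(components)
}

#' Group centroids in principal-component space
#'
#' @param pca A `cohort_pca`.
#' @param metadata Validated sample metadata covering the scored samples.
#' @param components Component indices (default: all).
#' @param groups Group specifiers (see [resolve_group()]); default: every
#'   cohort-timepoint group present.
#' @return Matrix of centroids, one row per group.
#' @export
group_centroids <- function(pca, metadata, components = NULL, groups = NULL) {
  stopifnot(inherits(pca, "cohort_pca"))
  comps <- resolve_components(pca, components)
  if (is.null(groups)) groups <- unique(sample_group(metadata))
  res <- vapply(groups, function(gl) {
    ids <- resolve_group(metadata, gl)
    ids <- intersect(ids, rownames(pca$scores))
    if (length(ids) == 0) stop("group '", gl, "' has no scored samples")
    colMeans(pca$scores[ids, comps, drop = FALSE])
  }, numeric(length(comps)))
  out <- if (is.matrix(res)) t(res) else matrix(res, ncol = 1)
  dimnames(out) <- list(groups, colnames(pca$scores)[comps])
  out
}

#' Euclidean distance between two group centroids
#'
#' Distances default to the full retained-component space; restricting
#' `components` (e.g. `c(2, 3)`) examines specific-subspace geometry.
#'
#' @inheritParams group_centroids
#' @param group_a,group_b Group specifiers.
#' @return A single distance (symmetric in `group_a`, `group_b`).
#' @export
centroid_distance <- function(pca, metadata, group_a, group_b,
                              components = NULL) {
  cen <- group_centroids(pca, metadata,
    components = components,
    groups = c(a = group_a, b = group_b)
  )
  sqrt(sum((cen[1, ] - cen[2, ])^2))
}
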