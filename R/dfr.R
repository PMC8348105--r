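#' Fit the healthy-control reference for the DFR score
#'
#' Computes per-gene control means M and unbiased (n - 1) variances V on the
#' variance-filtered log2 matrix of control samples. Genes with zero control
#' variance cannot be standardized and are dropped with a warning (recorded
#' in the returned object) rather than variance-floored, which would silently
#' deflate their contribution's scale.
#'
#' @param control_matrix Log2-scale `expr_matrix` of control samples only,
#'   restricted to the gene subset used for the PCA/DFR (>= 2 samples).
#' @return A `dfr_reference`: list with `gene_ids`, `M`, `V`, `n_controls`,
#'   `dropped` (zero-variance gene ids).
#' @export
fit_reference <- function(control_matrix) {
  stopifnot(inherits(control_matrix, "expr_matrix"))
  if (control_matrix$scale != "log2") stop("reference must be fit on log2 values")
  v <- control_matrix$values
  n <- ncol(v)
  if (n < 2) stop("need at least 2 control samples to fit a reference")
  M <- rowMeans(v)
  V <- row_vars(v)
  zero <- V == 0
  if (all(zero)) stop("every gene has zero control variance; cannot fit reference")
  dropped <- rownames(v)[zero]
  if (length(dropped)) {
    warning(
      "dropping ", length(dropped), " zero-variance gene(s) from the reference: ",
      paste(utils::head(dropped, 5), collapse = ", "),
      if (length(dropped) > 5) ", ..." else ""
    )
  }
  keep <- !zero
  structure(
    list(
      gene_ids = rownames(v)[keep],
      M = unname(M[keep]),
      V = unname(V[keep]),
      n_controls = n,
      dropped = dropped
    ),
    class = "dfr_reference"
  )
}

#' @export
print.dfr_reference <- function(x, ...) {
  cat(sprintf(
    "dfr_reference: %d genes, %d controls (%d dropped for zero variance)\n",
    length(x$gene_ids), x$n_controls, length(x$dropped)
  ))
  invisible(x)
}

#' Distance From Reference (DFR) score of one sample
#'
#' DFR = ln sum_i (e_i - M_i)^2 / V_i over the reference genes, where e_i is
#' the sample's log2 expression, and M_i and V_i the control mean and
#' variance. Standardizing each squared deviation by the control variance
#' prevents inherently variable or highly expressed genes from dominating
#' the score.
#'
#' @param sample_values Named numeric vector of log2 expression covering
#'   every reference gene.
#' @param ref A `dfr_reference`.
#' @return The DFR value (ln expression units).
#' @export
dfr_score <- function(sample_values, ref) {
  stopifnot(inherits(ref, "dfr_reference"))
  if (is.null(names(sample_values))) stop("`sample_values` must be named by gene id")
  miss <- setdiff(ref$gene_ids, names(sample_values))
  if (length(miss)) {
    stop(
      "sample is missing reference gene(s): ",
      paste(utils::head(miss, 5), collapse = ", ")
    )
  }
  e <- sample_values[ref$gene_ids]
  ssq <- sum((e - ref$M)^2 / ref$V)
  if (ssq == 0) stop("degenerate sample: expression identical to reference means")
  log(ssq)
}

#' DFR scores for every sample of a cohort
#'
#' @param m Log2-scale `expr_matrix` covering the reference genes.
#' @param ref A `dfr_reference`.
#' @return Named numeric vector of DFR values, one per sample.
#' @export
dfr_cohort <- function(m, ref) {
  stopifnot(inherits(m, "expr_matrix"), inherits(ref, "dfr_reference"))
  miss <- setdiff(ref$gene_ids, rownames(m$values))
  if (length(miss)) {
    stop(
      "matrix is missing reference gene(s): ",
      paste(utils::head(miss, 5), collapse = ", ")
    )
  }
  v <- m$values[ref$gene_ids, , drop = FALSE]
  ssq <- colSums((v - ref$M)^2 / ref$V)
  bad <- names(ssq)[ssq == 0]
  if (length(bad)) {
    stop("degenerate sample(s) identical to reference means: ", paste(bad, collapse = ", "))
  }
  log(ssq)
}

#' DFR scores of the control samples themselves
#'
#' In-sample scoring (`"in_sample"`, the default) fits the reference on all
#' controls and scores each against it; with the unbiased control variance
#' this pins the total standardized sum of squares across controls at
#' G * (n - 1). Leave-one-out scoring (`"leave_one_out"`) refits the
#' reference without the scored control, giving an out-of-sample view.
#'
#' @param control_matrix Log2-scale `expr_matrix` of controls (>= 3 for
#'   leave-one-out).
#' @param method Scoring protocol.
#' @return Named numeric vector of control DFR values.
#' @export
dfr_control_scores <- function(control_matrix,
                               method = c("in_sample", "leave_one_out")) {
  method <- match.arg(method)
  stopifnot(inherits(control_matrix, "expr_matrix"))
  if (method == "in_sample") {
    ref <- fit_reference(control_matrix)
    return(dfr_cohort(control_matrix, ref))
  }
  ids <- colnames(control_matrix$values)
  if (length(ids) < 3) stop("leave-one-out scoring needs at least 3 controls")
  out <- vapply(ids, function(id) {
    ref <- fit_reference(subset_samples(control_matrix, setdiff(ids, id)))
    dfr_score(control_matrix$values[, id], ref)
  }, numeric(1))
  out
}

#' Per-group DFR summaries with normality-gated pairwise tests
#'
#' Reports mean +/- SD of the DFR per group, and for every pair of groups a
#' two-sided comparison: if Shapiro-Wilk does not reject normality in either
#' group (alpha = 0.05) a Welch t-test is used, otherwise a Mann-Whitney
#' test; the test actually used is reported. Pairs involving a group smaller
#' than 3 samples are skipped with a warning (Shapiro-Wilk needs >= 3).
#'
#' @param scores Named DFR vector as returned by [dfr_cohort()].
#' @param metadata Validated sample metadata covering every scored sample.
#' @param groups Optional named group label vector (names = sample ids);
#'   defaults to [sample_group()] of the metadata.
#' @return A `dfr_group_summary`: list with `summary` (group, n, mean, sd)
#'   and `comparisons` (group_a, group_b, test, p).
#' @export
summarize_groups <- function(scores, metadata, groups = NULL) {
  if (is.null(groups)) groups <- sample_group(metadata)
  g <- groups[names(scores)]
  if (anyNA(g)) {
    stop(
      "unlabelled sample(s): ",
      paste(names(scores)[is.na(g)], collapse = ", ")
    )
  }
  labs <- unique(g)
  summ <- data.frame(
    group = labs,
    n = vapply(labs, function(l) sum(g == l), integer(1)),
    mean = vapply(labs, function(l) mean(scores[g == l]), numeric(1)),
    sd = vapply(labs, function(l) stats::sd(scores[g == l]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  comparisons <- NULL
  if (length(labs) >= 2) {
    pairs <- utils::combn(labs, 2)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1, k]
      b <- pairs[2, k]
      xa <- scores[g == a]
      xb <- scores[g == b]
      if (length(xa) < 3 || length(xb) < 3) {
        warning("skipping comparison ", a, " vs ", b, ": group smaller than 3")
        return(data.frame(
          group_a = a, group_b = b, test = "skipped",
          p = NA_real_, stringsAsFactors = FALSE
        ))
      }
      normal <- stats::shapiro.test(xa)$p.value >= 0.05 &&
        stats::shapiro.test(xb)$p.value >= 0.05
      if (normal) {
        res <- stats::t.test(xa, xb, var.equal = FALSE)
        test <- "t-test"
      } else {
        res <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE))
        test <- "Mann-Whitney"
      }
      data.frame(
        group_a = a, group_b = b, test = test,
        p = unname(res$p.value), stringsAsFactors = FALSE
      )
    }))
  }
  structure(list(summary = summ, comparisons = comparisons),
    class = "dfr_group_summary"
  )
}

#' @export
print.dfr_group_summary <- function(x, ...) {
  cat("DFR group summary (ln expression units):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-14s n=%3d  %.2f +/- %.2f\n",
      s$group[i], s$n[i], s$mean[i], s$sd[i]
    ))
  }
  if (!is.null(x$comparisons)) {
    cat("pairwise comparisons:\n")
    cc <- x$comparisons
    for (i in seq_len(nrow(cc))) {
      cat(sprintf(
        "  %s vs %s: %s, p = %.3g\n",
        cc$group_a[i], cc$group_b[i], cc$test[i], cc$p[i]
      ))
    }
  }
  invisible(x)
}
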