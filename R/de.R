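#' Per-gene fold changes between two groups
#'
#' The log2 fold change is mean(group A) - mean(group B) on the log2 scale;
#' the signed linear fold change follows the +FC / -FC convention:
#' +2^log2fc for up-regulation and -2^(-log2fc) for down-regulation, so a
#' halving is reported as -2 rather than 0.5.
#'
#' @param m Log2-scale `expr_matrix`.
#' @param metadata Validated sample metadata.
#' @param group_a,group_b Group specifiers (see [resolve_group()]); both must
#'   be non-empty.
#' @return Data.frame: `gene_id`, `log2fc`, `signed_fc`, `direction`
#'   (`up`/`down`, group A relative to group B).
#' @export
fold_changes <- function(m, metadata, group_a, group_b) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("fold changes expect log2-scale values")
  ia <- resolve_group(metadata, group_a)
  ib <- resolve_group(metadata, group_b)
  v <- m$values
  ma <- rowMeans(v[, ia, drop = FALSE])
  mb <- rowMeans(v[, ib, drop = FALSE])
  log2fc <- unname(ma - mb)
  data.frame(
    gene_id = rownames(v),
    log2fc = log2fc,
    signed_fc = ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc))),
    direction = ifelse(log2fc >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
}

# vectorized two-sided Welch t-test across matrix rows
row_welch_p <- function(v, ia, ib) {
  na <- length(ia)
  nb <- length(ib)
  if (na < 2 || nb < 2) stop("each group needs at least 2 samples for testing")
  xa <- v[, ia, drop = FALSE]
  xb <- v[, ib, drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  dfree <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), dfree)
  flat <- va == 0 & vb == 0 # no variance anywhere: p by the degenerate rule
  p[flat & ma == mb] <- 1
  p[flat & ma != mb] <- 0
  stats::setNames(p, rownames(v))
}

#' Per-gene two-sided Welch t-test p-values
#'
#' Genes with zero variance in both groups get p = 1 when the group means
#' are equal (no evidence of change) and p = 0 otherwise.
#'
#' @inheritParams fold_changes
#' @return Named numeric vector of p-values.
#' @export
de_test <- function(m, metadata, group_a, group_b) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("testing expects log2-scale values")
  ia <- resolve_group(metadata, group_a)
  ib <- resolve_group(metadata, group_b)
  row_welch_p(m$values, ia, ib)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjusted values (q-values) in the input order, computed within
#' one comparison's family of tests.
#'
#' @param p Numeric p-values, all in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || length(p) == 0 || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric and lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Full differential-expression records for one comparison
#'
#' Combines [fold_changes()], [de_test()] and [bh_adjust()]; the BH family is
#' all genes of this single comparison.
#'
#' @inheritParams fold_changes
#' @return Data.frame: `gene_id`, `log2fc`, `signed_fc`, `p`, `q`,
#'   `direction`.
#' @export
de_records <- function(m, metadata, group_a, group_b) {
  fc <- fold_changes(m, metadata, group_a, group_b)
  p <- de_test(m, metadata, group_a, group_b)
  fc$p <- unname(p[fc$gene_id])
  fc$q <- bh_adjust(fc$p)
  fc[, c("gene_id", "log2fc", "signed_fc", "p", "q", "direction")]
}

#' Gene-selection criteria
#'
#' Three selection modes, all with strict inequalities:
#' `fc_and_fdr` keeps genes with |signed fold change| > `fc_threshold` and
#' q < `q_threshold` (defaults 2 and 1e-4, used for patient-vs-control
#' contrasts); `p_only` keeps p < `p_threshold` (default 0.001, direct
#' CCI-vs-RAP contrasts); `fdr_only` keeps q < `q_threshold` (default 0.001,
#' disposition contrasts).
#'
#' @param mode Selection mode.
#' @param fc_threshold Linear fold-change threshold (> 0).
#' @param p_threshold,q_threshold Significance thresholds (> 0); `NULL`
#'   q_threshold takes the mode's default.
#' @return A `selection_criteria` list.
#' @export
de_criteria <- function(mode = c("fc_and_fdr", "p_only", "fdr_only"),
                        fc_threshold = 2, p_threshold = 0.001,
                        q_threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(q_threshold)) {
    q_threshold <- if (mode == "fc_and_fdr") 1e-4 else 1e-3
  }
  if (fc_threshold <= 0 || p_threshold <= 0 || q_threshold <= 0) {
    stop("selection thresholds must be positive")
  }
  structure(
    list(
      mode = mode, fc_threshold = fc_threshold,
      p_threshold = p_threshold, q_threshold = q_threshold
    ),
    class = "selection_criteria"
  )
}

#' Select differentially expressed genes
#'
#' @param records Data.frame from [de_records()].
#' @param criteria A `selection_criteria`.
#' @return Character vector of selected gene ids (record order); may be
#'   empty.
#' @export
select_genes <- function(records, criteria) {
  stopifnot(inherits(criteria, "selection_criteria"))
  keep <- switch(criteria$mode,
    fc_and_fdr = abs(records$signed_fc) > criteria$fc_threshold &
      records$q < criteria$q_threshold,
    p_only = records$p < criteria$p_threshold,
    fdr_only = records$q < criteria$q_threshold
  )
  records$gene_id[keep]
}

#' Direction concordance of two gene sets
#'
#' Intersects two selected gene sets and reports the percentage of common
#' genes whose up/down direction agrees between the two comparisons'
#' records. An empty intersection yields `NA` (not 0).
#'
#' @param records_a,records_b DE records of the two comparisons; each must
#'   cover every gene of its set.
#' @param set_a,set_b Selected gene-id vectors.
#' @return List: `n_common`, `percent_same_direction`, `common` (data.frame
#'   of common genes with both directions).
#' @export
concordance <- function(records_a, records_b, set_a, set_b) {
  common <- sort(intersect(set_a, set_b))
  if (length(common) == 0) {
    return(list(
      n_common = 0L, percent_same_direction = NA_real_,
      common = data.frame(
        gene_id = character(0), direction_a = character(0),
        direction_b = character(0), stringsAsFactors = FALSE
      )
    ))
  }
  miss <- c(setdiff(common, records_a$gene_id), setdiff(common, records_b$gene_id))
  if (length(miss)) stop("records missing gene(s): ", paste(miss, collapse = ", "))
  da <- records_a$direction[match(common, records_a$gene_id)]
  db <- records_b$direction[match(common, records_b$gene_id)]
  list(
    n_common = length(common),
    percent_same_direction = 100 * mean(da == db),
    common = data.frame(
      gene_id = common, direction_a = da, direction_b = db,
      stringsAsFactors = FALSE
    )
  )
}

#' Overlap between two gene sets
#'
#' @param set_a,set_b Gene-id vectors.
#' @return List: `n_common` and `genes` (sorted intersection).
#' @export
overlap_report <- function(set_a, set_b) {
  genes <- sort(intersect(set_a, set_b))
  list(n_common = length(genes), genes = genes)
}
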