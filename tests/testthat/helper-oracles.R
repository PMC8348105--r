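# independent oracles and shared fixtures for the suite

# brute-force Benjamini-Hochberg: q_(i) = min_{j >= i} m * p_(j) / j, clipped
# at 1, mapped back to input order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  q
}

# brute-force knee: explicit point-to-line distance from every normalized
# point to the chord joining the first and last points
elbow_oracle <- function(variances) {
  vs <- sort(variances, decreasing = TRUE)
  n <- length(vs)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (vs - min(vs)) / (max(vs) - min(vs))
  x1 <- 0
  y1 <- y[1]
  x2 <- 1
  y2 <- y[n]
  d <- vapply(seq_len(n), function(i) {
    abs((y2 - y1) * x[i] - (x2 - x1) * y[i] + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
  }, numeric(1))
  vs[which.max(d)]
}

# down-scaled cohort configuration used where full study-scale sizes are not
# the point of the test
small_config <- function(...) {
  base <- list(
    n_genes = 600, n_controls = 16,
    n_cci_day1 = 10, n_rap_day1 = 10, n_cci_day14 = 10, n_rap_day14 = 10,
    n_shared_storm_genes = 60, n_cci_specific_genes = 15,
    n_rap_specific_genes = 15, n_d14_signature_genes = 30,
    n_disposition_genes = 20, seed = 101
  )
  do.call(cohort_config, utils::modifyList(base, list(...)))
}

# cohort with no planted effects at all (noise-only null)
null_config <- function(...) {
  small_config(effect_mean_log2 = 0, effect_sd_log2 = 0, ...)
}

# tiny labelled expression fixture built in code
toy_matrix <- function(values, genes = NULL, samples = NULL, scale = "log2") {
  genes <- genes %||% paste0("g", seq_len(nrow(values)))
  samples <- samples %||% paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# metadata for a two-group layout used by DE unit tests
two_group_metadata <- function(ids_a, ids_b) {
  data.frame(
    sample_id = c(ids_a, ids_b),
    cohort = c(rep("CCI", length(ids_a)), rep("control", length(ids_b))),
    timepoint = c(rep("day1", length(ids_a)), rep("none", length(ids_b))),
    disposition = NA_character_,
    stringsAsFactors = FALSE
  )
}
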