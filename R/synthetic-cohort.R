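#' Configuration for a synthetic sepsis-survivor expression cohort
#'
#' Parameterizes a ground-truth-labelled cohort with the structure the
#' downstream analyses assume: healthy controls; CCI and rapid-recovery (RAP)
#' patients sampled at day 1 and day 14 post-sepsis; a large day-1 "genomic
#' storm" gene module perturbed in the same direction in both trajectories;
#' smaller trajectory-specific day-1 modules; a day-14 signature module
#' disjoint from all day-1 modules; partial, trajectory-dependent return of
#' day-1 effects toward baseline at day 14; and positive disposition effects
#' in poor-disposition CCI day-14 samples. A fraction of genes receives a
#' higher baseline standard deviation, producing an elbow in the sorted
#' per-gene variance curve.
#'
#' Expression is generated directly on the log2 scale with Gaussian per-gene
#' noise.
#'
#' @param n_genes Number of genes.
#' @param n_controls Number of healthy control samples.
#' @param n_cci_day1,n_rap_day1,n_cci_day14,n_rap_day14 Patient group sizes.
#' @param n_shared_storm_genes Genes perturbed at day 1 in both trajectories,
#'   with a single shared direction per gene.
#' @param n_cci_specific_genes,n_rap_specific_genes Day-1 genes perturbed in
#'   one trajectory only.
#' @param n_d14_signature_genes Day-14 signature genes (perturbed in CCI
#'   day-14 samples at full effect), drawn disjoint from every day-1 module.
#' @param n_disposition_genes Genes upregulated in poor- versus
#'   good-disposition CCI day-14 samples (always positive effects).
#' @param effect_mean_log2,effect_sd_log2 Normal distribution of per-gene
#'   perturbation magnitudes, log2 units.
#' @param return_fraction_cci,return_fraction_rap Fraction (0..1) of each
#'   trajectory's day-1 effect retained at day 14.
#' @param baseline_mean_range Length-2 range (log2 units) for uniform per-gene
#'   baseline means.
#' @param baseline_sd_low,baseline_sd_high Per-gene noise SD tiers (log2
#'   units).
#' @param high_var_fraction Fraction of genes assigned `baseline_sd_high`.
#' @param disposition_split Fraction of CCI day-14 samples labelled poor.
#' @param disposition_split_rap Fraction of RAP day-14 samples labelled poor
#'   (labels only; no planted effect).
#' @param seed Integer seed; identical configs generate identical cohorts.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_genes = 5000,
                          n_controls = 40,
                          n_cci_day1 = 20,
                          n_rap_day1 = 20,
                          n_cci_day14 = 20,
                          n_rap_day14 = 20,
                          n_shared_storm_genes = 400,
                          n_cci_specific_genes = 100,
                          n_rap_specific_genes = 100,
                          n_d14_signature_genes = 150,
                          n_disposition_genes = 100,
                          effect_mean_log2 = 2.5,
                          effect_sd_log2 = 0.3,
                          return_fraction_cci = 0.7,
                          return_fraction_rap = 0.2,
                          baseline_mean_range = c(4, 12),
                          baseline_sd_low = 0.3,
                          baseline_sd_high = 0.9,
                          high_var_fraction = 0.2,
                          disposition_split = 0.75,
                          disposition_split_rap = 0.33,
                          seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_controls = n_controls,
    n_cci_day1 = n_cci_day1, n_rap_day1 = n_rap_day1,
    n_cci_day14 = n_cci_day14, n_rap_day14 = n_rap_day14,
    n_shared_storm_genes = n_shared_storm_genes,
    n_cci_specific_genes = n_cci_specific_genes,
    n_rap_specific_genes = n_rap_specific_genes,
    n_d14_signature_genes = n_d14_signature_genes,
    n_disposition_genes = n_disposition_genes,
    effect_mean_log2 = effect_mean_log2, effect_sd_log2 = effect_sd_log2,
    return_fraction_cci = return_fraction_cci,
    return_fraction_rap = return_fraction_rap,
    baseline_mean_range = baseline_mean_range,
    baseline_sd_low = baseline_sd_low, baseline_sd_high = baseline_sd_high,
    high_var_fraction = high_var_fraction,
    disposition_split = disposition_split,
    disposition_split_rap = disposition_split_rap,
    seed = as.integer(seed)
  )
  counts <- c(
    "n_genes", "n_controls", "n_cci_day1", "n_rap_day1", "n_cci_day14",
    "n_rap_day14", "n_shared_storm_genes", "n_cci_specific_genes",
    "n_rap_specific_genes", "n_d14_signature_genes", "n_disposition_genes"
  )
  for (nm in counts) {
    v <- cfg[[nm]]
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      stop("configuration error: `", nm, "` must be a single non-negative integer")
    }
    cfg[[nm]] <- as.integer(v)
  }
  fracs <- c(
    "return_fraction_cci", "return_fraction_rap", "high_var_fraction",
    "disposition_split", "disposition_split_rap"
  )
  for (nm in fracs) {
    v <- cfg[[nm]]
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("configuration error: `", nm, "` must lie in [0, 1]")
    }
  }
  if (cfg$effect_sd_log2 < 0 || cfg$baseline_sd_low <= 0 || cfg$baseline_sd_high <= 0) {
    stop("configuration error: noise/effect SDs must be positive")
  }
  if (length(cfg$baseline_mean_range) != 2 ||
    cfg$baseline_mean_range[1] > cfg$baseline_mean_range[2]) {
    stop("configuration error: `baseline_mean_range` must be an increasing length-2 range")
  }
  n_planted <- cfg$n_shared_storm_genes + cfg$n_cci_specific_genes +
    cfg$n_rap_specific_genes + cfg$n_d14_signature_genes +
    cfg$n_disposition_genes
  if (n_planted > cfg$n_genes) {
    stop(
      "configuration error: planted gene sets (", n_planted,
      ") exceed n_genes (", cfg$n_genes, ")"
    )
  }
  structure(cfg, class = "cohort_config")
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' The file must contain only `cohort_config()` field names.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(cohort_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(cohort_config, vals)
}

#' Generate a ground-truth-labelled synthetic cohort
#'
#' Per-gene baseline means are uniform over `baseline_mean_range`; a
#' `high_var_fraction` subset of genes receives noise SD `baseline_sd_high`,
#' the rest `baseline_sd_low`. Planted gene modules are drawn without
#' replacement and mutually disjoint; each planted gene gets one effect
#' magnitude ~ Normal(`effect_mean_log2`, `effect_sd_log2`) and one direction
#' from a shared direction field, so storm genes shift the same way in both
#' trajectories. Day-14 samples retain `return_fraction * effect` on their
#' trajectory's day-1 genes; CCI day-14 samples additionally carry the full
#' day-14 signature effects, and the poor-disposition subset of them carries
#' positive disposition effects.
#'
#' @param config A `cohort_config`.
#' @return A `synthetic_cohort`: list with `expression` (log2 `expr_matrix`),
#'   `metadata` (data.frame), `truth` (per gene/role/cohort/timepoint planted
#'   effect and sign) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created by cohort_config()")
  }
  set.seed(config$seed)
  ng <- config$n_genes
  gid <- sprintf("g%05d", seq_len(ng))

  # baseline structure
  mu <- stats::runif(ng, config$baseline_mean_range[1], config$baseline_mean_range[2])
  sd_g <- rep(config$baseline_sd_low, ng)
  n_high <- round(config$high_var_fraction * ng)
  if (n_high > 0) sd_g[sample.int(ng, n_high)] <- config$baseline_sd_high

  # shared direction field and per-gene effect magnitudes
  dir_field <- sample(c(-1L, 1L), ng, replace = TRUE)
  eff_g <- stats::rnorm(ng, config$effect_mean_log2, config$effect_sd_log2)

  # disjoint planted modules
  sizes <- c(
    storm = config$n_shared_storm_genes,
    cci = config$n_cci_specific_genes,
    rap = config$n_rap_specific_genes,
    d14 = config$n_d14_signature_genes,
    dispo = config$n_disposition_genes
  )
  pool <- if (sum(sizes) > 0) sample.int(ng, sum(sizes)) else integer(0)
  idx <- split(pool, rep(names(sizes), sizes))
  storm <- sort(idx[["storm"]] %||% integer(0))
  cci_sp <- sort(idx[["cci"]] %||% integer(0))
  rap_sp <- sort(idx[["rap"]] %||% integer(0))
  d14_sig <- sort(idx[["d14"]] %||% integer(0))
  dispo <- sort(idx[["dispo"]] %||% integer(0))

  # per-group mean shifts (log2 units)
  shift <- function(ix, frac = 1) {
    d <- numeric(ng)
    d[ix] <- frac * dir_field[ix] * eff_g[ix]
    d
  }
  d_cci1 <- shift(c(storm, cci_sp))
  d_rap1 <- shift(c(storm, rap_sp))
  d_cci14 <- shift(c(storm, cci_sp), config$return_fraction_cci) + shift(d14_sig)
  d_rap14 <- shift(c(storm, rap_sp), config$return_fraction_rap)
  d_dispo <- numeric(ng)
  d_dispo[dispo] <- abs(eff_g[dispo]) # strictly positive in poor vs good

  block <- function(n_s, delta) {
    if (n_s == 0) {
      return(matrix(numeric(0), ng, 0))
    }
    mu + delta + matrix(stats::rnorm(ng * n_s, 0, sd_g), ng, n_s)
  }

  n_poor_cci <- round(config$disposition_split * config$n_cci_day14)
  n_poor_rap <- round(config$disposition_split_rap * config$n_rap_day14)

  ctrl <- block(config$n_controls, numeric(ng))
  cci1 <- block(config$n_cci_day1, d_cci1)
  rap1 <- block(config$n_rap_day1, d_rap1)
  cci14 <- block(config$n_cci_day14, d_cci14)
  if (n_poor_cci > 0 && length(dispo) > 0) {
    poor_cols <- seq.int(config$n_cci_day14 - n_poor_cci + 1, config$n_cci_day14)
    cci14[, poor_cols] <- cci14[, poor_cols] + d_dispo
  }
  rap14 <- block(config$n_rap_day14, d_rap14)

  vals <- cbind(ctrl, cci1, rap1, cci14, rap14)
  rownames(vals) <- gid
  sid <- c(
    sprintf("ctrl_%03d", seq_len(config$n_controls)),
    sprintf("cci_d1_%03d", seq_len(config$n_cci_day1)),
    sprintf("rap_d1_%03d", seq_len(config$n_rap_day1)),
    sprintf("cci_d14_%03d", seq_len(config$n_cci_day14)),
    sprintf("rap_d14_%03d", seq_len(config$n_rap_day14))
  )
  colnames(vals) <- sid

  dispo_cci <- rep(NA_character_, config$n_cci_day14)
  if (config$n_cci_day14 > 0) {
    dispo_cci <- rep("good", config$n_cci_day14)
    if (n_poor_cci > 0) dispo_cci[seq.int(config$n_cci_day14 - n_poor_cci + 1, config$n_cci_day14)] <- "poor"
  }
  dispo_rap <- rep(NA_character_, config$n_rap_day14)
  if (config$n_rap_day14 > 0) {
    dispo_rap <- rep("good", config$n_rap_day14)
    if (n_poor_rap > 0) dispo_rap[seq.int(config$n_rap_day14 - n_poor_rap + 1, config$n_rap_day14)] <- "poor"
  }
  metadata <- data.frame(
    sample_id = sid,
    cohort = c(
      rep("control", config$n_controls),
      rep("CCI", config$n_cci_day1), rep("RAP", config$n_rap_day1),
      rep("CCI", config$n_cci_day14), rep("RAP", config$n_rap_day14)
    ),
    timepoint = c(
      rep("none", config$n_controls),
      rep("day1", config$n_cci_day1 + config$n_rap_day1),
      rep("day14", config$n_cci_day14 + config$n_rap_day14)
    ),
    disposition = c(
      rep(NA_character_, config$n_controls),
      rep(NA_character_, config$n_cci_day1 + config$n_rap_day1),
      dispo_cci, dispo_rap
    ),
    stringsAsFactors = FALSE
  )

  truth_row <- function(ix, role, cohort, timepoint, frac = 1, sign = NULL) {
    if (length(ix) == 0) {
      return(NULL)
    }
    data.frame(
      gene_id = gid[ix], role = role, cohort = cohort, timepoint = timepoint,
      effect_log2 = frac * eff_g[ix],
      sign = if (is.null(sign)) dir_field[ix] else rep(sign, length(ix)),
      stringsAsFactors = FALSE
    )
  }
  rf_c <- config$return_fraction_cci
  rf_r <- config$return_fraction_rap
  rows <- Filter(Negate(is.null), list(
    truth_row(storm, "storm", "CCI", "day1"),
    truth_row(storm, "storm", "RAP", "day1"),
    truth_row(cci_sp, "cci_specific", "CCI", "day1"),
    truth_row(rap_sp, "rap_specific", "RAP", "day1"),
    truth_row(storm, "storm", "CCI", "day14", rf_c),
    truth_row(storm, "storm", "RAP", "day14", rf_r),
    truth_row(cci_sp, "cci_specific", "CCI", "day14", rf_c),
    truth_row(rap_sp, "rap_specific", "RAP", "day14", rf_r),
    truth_row(d14_sig, "day14_signature", "CCI", "day14"),
    truth_row(dispo, "disposition", "CCI", "day14", sign = 1L)
  ))
  truth <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(
      gene_id = character(0), role = character(0), cohort = character(0),
      timepoint = character(0), effect_log2 = numeric(0), sign = integer(0)
    )
  }
  if (length(dispo)) {
    truth$effect_log2[truth$role == "disposition"] <- abs(eff_g[dispo])
  }

  structure(
    list(
      expression = expr_matrix(vals, scale = "log2"),
      metadata = metadata,
      truth = truth,
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d genes x %d samples, %d planted truth records (seed %d)\n",
    nrow(x$expression$values), ncol(x$expression$values), nrow(x$truth),
    x$config$seed
  ))
  invisible(x)
}

#' Planted ground-truth gene set for a contrast
#'
#' Returns the genes (and their expected direction of change, first-named
#' group relative to second) planted for one of the pipeline's contrasts.
#' For the direct CCI-vs-RAP contrast at day 14 the declared signature is the
#' day-14 module (planted in CCI only); residual day-1 effects that differ
#' between trajectories through their return fractions are not part of the
#' declared signature. Zero-effect entries (e.g. a return fraction of 0) are
#' excluded.
#'
#' @param cohort A `synthetic_cohort`.
#' @param comparison One of `"CCI_day1_vs_control"`, `"RAP_day1_vs_control"`,
#'   `"CCI_day14_vs_control"`, `"RAP_day14_vs_control"`,
#'   `"CCI_vs_RAP_day1"`, `"CCI_vs_RAP_day14"`, `"poor_vs_good_CCI_day14"`.
#' @return Data.frame with `gene_id`, `sign` (+1 up, -1 down) and
#'   `effect_log2`, ordered by gene id.
#' @export
ground_truth_set <- function(cohort, comparison) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tr <- cohort$truth
  pick <- function(roles, cohort_lab, timepoint, flip = integer(0)) {
    rows <- tr[tr$role %in% roles & tr$cohort == cohort_lab &
      tr$timepoint == timepoint & tr$effect_log2 != 0, , drop = FALSE]
    sgn <- rows$sign
    sgn[rows$role %in% flip] <- -sgn[rows$role %in% flip]
    out <- data.frame(
      gene_id = rows$gene_id, sign = sgn,
      effect_log2 = abs(rows$effect_log2), stringsAsFactors = FALSE
    )
    out[order(out$gene_id), , drop = FALSE]
  }
  out <- switch(comparison,
    CCI_day1_vs_control = pick(c("storm", "cci_specific"), "CCI", "day1"),
    RAP_day1_vs_control = pick(c("storm", "rap_specific"), "RAP", "day1"),
    CCI_day14_vs_control = {
      a <- pick(c("storm", "cci_specific"), "CCI", "day14")
      b <- pick("day14_signature", "CCI", "day14")
      x <- rbind(a, b)
      x[order(x$gene_id), , drop = FALSE]
    },
    RAP_day14_vs_control = pick(c("storm", "rap_specific"), "RAP", "day14"),
    CCI_vs_RAP_day1 = {
      a <- pick("cci_specific", "CCI", "day1")
      b <- pick("rap_specific", "RAP", "day1")
      b$sign <- -b$sign # higher in RAP means lower in CCI-vs-RAP
      x <- rbind(a, b)
      x[order(x$gene_id), , drop = FALSE]
    },
    CCI_vs_RAP_day14 = pick("day14_signature", "CCI", "day14"),
    poor_vs_good_CCI_day14 = pick("disposition", "CCI", "day14"),
    stop("unknown comparison: ", comparison)
  )
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes `expression.tsv` (genes x samples, with a scale comment line),
#' `metadata.tsv` and `truth.tsv` under `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression(cohort$expression, paths[["expression"]])
  write_metadata(cohort$metadata, paths[["metadata"]])
  utils::write.table(cohort$truth, paths[["truth"]],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}
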