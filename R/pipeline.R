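#' Default comparison plan
#'
#' The standard contrasts: each patient group versus controls at each day
#' (fold change > |2| and FDR Q < 1e-4), direct CCI-vs-RAP per day
#' (p < 0.001), and disposition poor-vs-good at day 14 within CCI and within
#' all sepsis survivors (FDR Q < 0.001). Poor is listed first in the
#' disposition contrasts so `up` means higher expression in poor.
#'
#' @return Named list of comparisons, each a list with `a`, `b` (group
#'   specifiers) and `criteria`.
#' @export
default_comparisons <- function() {
  list(
    cci_day1_vs_control = list(
      a = "CCI_day1", b = "control",
      criteria = de_criteria("fc_and_fdr")
    ),
    rap_day1_vs_control = list(
      a = "RAP_day1", b = "control",
      criteria = de_criteria("fc_and_fdr")
    ),
    cci_day14_vs_control = list(
      a = "CCI_day14", b = "control",
      criteria = de_criteria("fc_and_fdr")
    ),
    rap_day14_vs_control = list(
      a = "RAP_day14", b = "control",
      criteria = de_criteria("fc_and_fdr")
    ),
    cci_vs_rap_day1 = list(
      a = "CCI_day1", b = "RAP_day1",
      criteria = de_criteria("p_only")
    ),
    cci_vs_rap_day14 = list(
      a = "CCI_day14", b = "RAP_day14",
      criteria = de_criteria("p_only")
    ),
    disposition_cci_day14 = list(
      a = "CCI_day14_poor", b = "CCI_day14_good",
      criteria = de_criteria("fdr_only")
    ),
    disposition_all_day14 = list(
      a = "day14_poor", b = "day14_good",
      criteria = de_criteria("fdr_only")
    )
  )
}

#' Pipeline configuration
#'
#' Exactly one input mode: simulate (`cohort` is a `cohort_config`) or load
#' (`expression_path` + `metadata_path`).
#'
#' @param cohort A `cohort_config` for simulate mode, or `NULL`.
#' @param expression_path,metadata_path TSV paths for load mode, or `NULL`.
#' @param log2_offset Offset used if loaded data are on the linear scale.
#' @param cutoff Optional variance-cutoff override; default `NULL` derives
#'   the cutoff with [elbow_cutoff()].
#' @param comparisons Comparison plan (see [default_comparisons()]).
#' @param dfr_control_method How control DFR scores are computed
#'   (see [dfr_control_scores()]).
#' @param seed Integer seed for the whole run; in simulate mode it replaces
#'   the cohort config's seed so one number governs all randomness. `NULL`
#'   keeps the cohort config's own seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, expression_path = NULL,
                            metadata_path = NULL, log2_offset = 1,
                            cutoff = NULL,
                            comparisons = default_comparisons(),
                            dfr_control_method = c("in_sample", "leave_one_out"),
                            seed = NULL) {
  simulate <- !is.null(cohort)
  load <- !is.null(expression_path) || !is.null(metadata_path)
  if (simulate == load) {
    stop("provide exactly one of `cohort` or (`expression_path` + `metadata_path`)")
  }
  if (load && (is.null(expression_path) || is.null(metadata_path))) {
    stop("load mode needs both `expression_path` and `metadata_path`")
  }
  if (simulate && !inherits(cohort, "cohort_config")) {
    stop("`cohort` must be a cohort_config()")
  }
  if (!is.null(cutoff) && (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0)) {
    stop("`cutoff` must be a single non-negative number")
  }
  if (length(comparisons) == 0 || is.null(names(comparisons)) ||
    any(names(comparisons) == "")) {
    stop("`comparisons` must be a non-empty named list")
  }
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    if (!all(c("a", "b", "criteria") %in% names(cmp)) ||
      !inherits(cmp$criteria, "selection_criteria")) {
      stop("comparison '", nm, "' must have fields a, b and de_criteria() criteria")
    }
  }
  if (simulate && !is.null(seed)) {
    cohort$seed <- as.integer(seed)
  }
  structure(
    list(
      mode = if (simulate) "simulate" else "load",
      cohort = cohort, expression_path = expression_path,
      metadata_path = metadata_path, log2_offset = log2_offset,
      cutoff = cutoff, comparisons = comparisons,
      dfr_control_method = match.arg(dfr_control_method),
      seed = if (simulate) cohort$seed else seed
    ),
    class = "pipeline_config"
  )
}

#' Run the full trajectory-analysis pipeline
#'
#' Stages, in order: obtain data (simulate or load), log2-transform if
#' needed, validate that every configured comparison resolves to samples,
#' compute the variance profile and elbow cutoff, filter, fit the control
#' reference and score every sample's DFR, summarize DFR by group with
#' normality-gated tests, run centered/scaled PCA with group-centroid
#' distances to controls, run every configured DE comparison on the full
#' (unfiltered) gene set, and assemble concordance/overlap/disposition
#' reports. Deterministic given the seed.
#'
#' @param config A `pipeline_config`.
#' @param outdir Optional output directory; when given, all report tables
#'   are written as TSV plus a machine-readable `summary.json`.
#' @return A `run_report` list.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  # stage: data
  if (config$mode == "simulate") {
    cohort <- generate_cohort(config$cohort)
    expr <- cohort$expression
    metadata <- cohort$metadata
  } else {
    cohort <- NULL
    expr <- read_expression(config$expression_path)
    metadata <- read_metadata(config$metadata_path)
  }
  miss <- setdiff(sample_ids(expr), metadata$sample_id)
  if (length(miss)) {
    stop("stage data: samples absent from metadata: ", paste(miss, collapse = ", "))
  }
  if (expr$scale == "linear") expr <- log2_transform(expr, config$log2_offset)

  # stage: validation (before any computation on the values)
  for (nm in names(config$comparisons)) {
    cmp <- config$comparisons[[nm]]
    for (side in c("a", "b")) {
      ids <- tryCatch(resolve_group(metadata, cmp[[side]]), error = function(e) {
        stop("stage validation: comparison '", nm, "': ", conditionMessage(e),
          call. = FALSE
        )
      })
      if (length(ids) < 2) {
        stop(
          "stage validation: comparison '", nm, "' group '", cmp[[side]],
          "' has fewer than 2 samples"
        )
      }
    }
  }
  ctrl_ids <- resolve_group(metadata, "control")

  # stage: variance filter
  profile <- gene_variances(expr)
  cutoff <- config$cutoff %||% elbow_cutoff(profile)
  filtered <- withCallingHandlers(
    filter_by_variance(expr, profile, cutoff),
    message = function(m) invokeRestart("muffleMessage")
  )

  # stage: DFR
  ref <- fit_reference(subset_samples(filtered, ctrl_ids))
  patient_ids <- setdiff(sample_ids(expr), ctrl_ids)
  scores <- c(
    dfr_control_scores(subset_samples(filtered, ctrl_ids),
      method = config$dfr_control_method
    ),
    dfr_cohort(subset_samples(filtered, patient_ids), ref)
  )[sample_ids(expr)]
  dfr_summary <- summarize_groups(scores, metadata)

  # stage: PCA geometry
  pca <- run_pca(filtered)
  groups_present <- unique(sample_group(metadata))
  centroids <- group_centroids(pca, metadata, groups = groups_present)
  dist_groups <- setdiff(groups_present, "control")
  distances <- data.frame(
    group = dist_groups,
    distance_to_control = vapply(
      dist_groups,
      function(gl) centroid_distance(pca, metadata, gl, "control"),
      numeric(1)
    ),
    stringsAsFactors = FALSE, row.names = NULL
  )

  # stage: differential expression (full gene set)
  de <- lapply(names(config$comparisons), function(nm) {
    cmp <- config$comparisons[[nm]]
    records <- de_records(expr, metadata, cmp$a, cmp$b)
    selected <- select_genes(records, cmp$criteria)
    list(
      name = nm, a = cmp$a, b = cmp$b, criteria = cmp$criteria,
      records = records, selected = selected
    )
  })
  names(de) <- names(config$comparisons)

  # stage: set analysis
  conc <- list()
  for (day in c("day1", "day14")) {
    na <- paste0("cci_", day, "_vs_control")
    nb <- paste0("rap_", day, "_vs_control")
    if (!is.null(de[[na]]) && !is.null(de[[nb]])) {
      conc[[day]] <- concordance(
        de[[na]]$records, de[[nb]]$records,
        de[[na]]$selected, de[[nb]]$selected
      )
    }
  }
  overlap <- list()
  if (!is.null(de$cci_vs_rap_day1) && !is.null(de$cci_vs_rap_day14)) {
    overlap$selected_direct <- overlap_report(
      de$cci_vs_rap_day1$selected, de$cci_vs_rap_day14$selected
    )
  }
  if (!is.null(cohort)) {
    overlap$truth_direct <- overlap_report(
      ground_truth_set(cohort, "CCI_vs_RAP_day1")$gene_id,
      ground_truth_set(cohort, "CCI_vs_RAP_day14")$gene_id
    )
  }

  report <- structure(
    list(
      provenance = list(
        package_version = as.character(utils::packageVersion("septraj")),
        seed = config$seed,
        config_hash = fnv1a32(config_fingerprint(config)),
        n_genes = nrow(expr$values),
        n_samples = ncol(expr$values)
      ),
      cohort = cohort,
      expression = expr,
      metadata = metadata,
      variance = list(
        profile = profile, cutoff = cutoff,
        n_retained = nrow(filtered$values)
      ),
      dfr = list(scores = scores, reference = ref, summary = dfr_summary),
      pca = list(
        result = pca, var_explained = pca$var_explained,
        centroids = centroids, distances = distances
      ),
      de = de,
      concordance = conc,
      overlap = overlap
    ),
    class = "run_report"
  )
  report$disposition <- summarize_disposition(report)
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# stable text fingerprint of a pipeline config (for the provenance hash)
config_fingerprint <- function(config) {
  flat <- config
  flat$comparisons <- lapply(flat$comparisons, function(cmp) {
    cmp$criteria <- unclass(cmp$criteria)
    cmp
  })
  if (!is.null(flat$cohort)) flat$cohort <- unclass(flat$cohort)
  jsonlite::toJSON(unclass(flat), auto_unbox = TRUE, digits = NA, null = "null")
}

#' Direction uniformity of the disposition gene set
#'
#' For a disposition (poor vs good) comparison, reports how many genes were
#' selected and what percentage of them are expressed higher in the
#' poor-disposition group. An empty selection yields `NA`.
#'
#' @param report A `run_report`.
#' @param comparison Name of the disposition comparison in the report.
#' @return List: `comparison`, `n_selected`, `percent_up_in_poor`.
#' @export
summarize_disposition <- function(report, comparison = "disposition_cci_day14") {
  stopifnot(inherits(report, "run_report"))
  cmp <- report$de[[comparison]]
  if (is.null(cmp)) {
    return(list(
      comparison = comparison, n_selected = NA_integer_,
      percent_up_in_poor = NA_real_
    ))
  }
  sel <- cmp$selected
  if (length(sel) == 0) {
    return(list(
      comparison = comparison, n_selected = 0L,
      percent_up_in_poor = NA_real_
    ))
  }
  dirs <- cmp$records$direction[match(sel, cmp$records$gene_id)]
  list(
    comparison = comparison,
    n_selected = length(sel),
    percent_up_in_poor = 100 * mean(dirs == "up")
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "run_report: %d genes x %d samples (seed %s, config %s)\n",
    x$provenance$n_genes, x$provenance$n_samples,
    x$provenance$seed %||% "none", x$provenance$config_hash
  ))
  cat(sprintf(
    "variance filter: cutoff %.4g, %d genes retained\n",
    x$variance$cutoff, x$variance$n_retained
  ))
  print(x$dfr$summary)
  ve <- x$pca$var_explained
  cat(sprintf(
    "PCA: PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%%\n",
    100 * ve[1], 100 * ve[2], 100 * ve[min(3, length(ve))]
  ))
  for (nm in names(x$de)) {
    cat(sprintf("DE %s: %d genes selected\n", nm, length(x$de[[nm]]$selected)))
  }
  invisible(x)
}

# write all report tables as TSV plus a JSON run summary
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(outdir, name),
      sep = "\t", quote = FALSE,
      row.names = FALSE, na = "NA"
    )
  }
  groups <- sample_group(report$metadata)
  tsv(data.frame(
    sample_id = names(report$dfr$scores),
    group = unname(groups[names(report$dfr$scores)]),
    dfr = unname(report$dfr$scores), stringsAsFactors = FALSE
  ), "dfr_scores.tsv")
  tsv(report$dfr$summary$summary, "dfr_summary.tsv")
  if (!is.null(report$dfr$summary$comparisons)) {
    tsv(report$dfr$summary$comparisons, "dfr_comparisons.tsv")
  }
  tsv(data.frame(
    component = seq_along(report$pca$var_explained),
    var_explained = report$pca$var_explained
  ), "pca_variance.tsv")
  tsv(report$pca$distances, "pca_centroid_distances.tsv")
  for (nm in names(report$de)) {
    tsv(report$de[[nm]]$records, paste0("de_", nm, ".tsv"))
    writeLines(report$de[[nm]]$selected, file.path(outdir, paste0("geneset_", nm, ".txt")))
  }
  summary <- list(
    provenance = report$provenance,
    variance = list(
      cutoff = report$variance$cutoff,
      n_retained = report$variance$n_retained
    ),
    dfr_groups = report$dfr$summary$summary,
    pca_var_explained = report$pca$var_explained,
    centroid_distances = report$pca$distances,
    de_counts = lapply(report$de, function(d) length(d$selected)),
    concordance = lapply(report$concordance, function(cc) {
      cc[c("n_common", "percent_same_direction")]
    }),
    overlap = lapply(report$overlap, function(ov) ov["n_common"]),
    disposition = report$disposition
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(outdir)
}
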