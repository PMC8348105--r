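test_that("identical seeds reproduce a cohort exactly; different seeds do not", {
  a <- generate_cohort(small_config())
  b <- generate_cohort(small_config())
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(small_config(seed = 202))
  expect_false(identical(a$expression$values, c$expression$values))
})

test_that("cohort dimensions and labels follow the configuration", {
  cfg <- cohort_config(
    n_genes = 100, n_controls = 5,
    n_cci_day1 = 0, n_rap_day1 = 0, n_cci_day14 = 0, n_rap_day14 = 0,
    n_shared_storm_genes = 10, n_cci_specific_genes = 0,
    n_rap_specific_genes = 0, n_d14_signature_genes = 0,
    n_disposition_genes = 0, seed = 7
  )
  ch <- generate_cohort(cfg)
  expect_equal(dim(ch$expression$values), c(100, 5))
  expect_true(all(ch$metadata$cohort == "control"))
  expect_true(all(ch$metadata$timepoint == "none"))
  expect_true(all(is.na(ch$metadata$disposition)))
  expect_identical(ch$expression$scale, "log2")

  full <- generate_cohort(small_config())
  expect_equal(
    dim(full$expression$values),
    c(600, 16 + 10 + 10 + 10 + 10)
  )
  expect_equal(sum(full$metadata$cohort == "control"), 16)
  expect_equal(sum(full$metadata$timepoint == "day14"), 20)
  n_poor_cci <- sum(full$metadata$cohort == "CCI" &
    !is.na(full$metadata$disposition) & full$metadata$disposition == "poor")
  expect_equal(n_poor_cci, round(0.75 * 10))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_genes = -5), "non-negative")
  expect_error(cohort_config(n_controls = 2.5), "non-negative integer")
  expect_error(
    cohort_config(n_genes = 100, n_shared_storm_genes = 200),
    "exceed"
  )
  expect_error(cohort_config(return_fraction_cci = 1.5), "\\[0, 1\\]")
  expect_error(cohort_config(high_var_fraction = -0.1), "\\[0, 1\\]")
  expect_error(cohort_config(baseline_sd_low = 0), "positive")
  expect_error(generate_cohort(list(n_genes = 10)), "cohort_config")
})

test_that("ground-truth sets have the planted sizes, signs and disjointness", {
  ch <- generate_cohort(small_config())
  cci1 <- ground_truth_set(ch, "CCI_day1_vs_control")
  rap1 <- ground_truth_set(ch, "RAP_day1_vs_control")
  expect_equal(nrow(cci1), 60 + 15)
  expect_equal(nrow(rap1), 60 + 15)
  expect_true(all(cci1$sign %in% c(-1L, 1L)))
  # shared storm genes carry the same direction in both trajectories
  storm <- intersect(cci1$gene_id, rap1$gene_id)
  expect_length(storm, 60)
  expect_identical(
    cci1$sign[match(storm, cci1$gene_id)],
    rap1$sign[match(storm, rap1$gene_id)]
  )
  # direct day-1 and day-14 signatures are disjoint by construction
  d1 <- ground_truth_set(ch, "CCI_vs_RAP_day1")
  d14 <- ground_truth_set(ch, "CCI_vs_RAP_day14")
  expect_equal(nrow(d1), 30)
  expect_equal(nrow(d14), 30)
  expect_length(intersect(d1$gene_id, d14$gene_id), 0)
  # disposition effects are strictly positive in poor
  dis <- ground_truth_set(ch, "poor_vs_good_CCI_day14")
  expect_equal(nrow(dis), 20)
  expect_true(all(dis$sign == 1L))
  expect_error(ground_truth_set(ch, "no_such_contrast"), "unknown comparison")
})

test_that("a cohort without planted modules yields empty truth sets", {
  ch <- generate_cohort(small_config(
    n_shared_storm_genes = 0, n_cci_specific_genes = 0,
    n_rap_specific_genes = 0, n_d14_signature_genes = 0,
    n_disposition_genes = 0
  ))
  expect_equal(nrow(ground_truth_set(ch, "CCI_day1_vs_control")), 0)
  expect_equal(nrow(ch$truth), 0)
})

test_that("group-mean differences converge to the planted effects", {
  # large patient group so the law of large numbers pins the empirical
  # effect at the planted value
  cfg <- cohort_config(
    n_genes = 60, n_controls = 200, n_cci_day1 = 500,
    n_rap_day1 = 0, n_cci_day14 = 0, n_rap_day14 = 0,
    n_shared_storm_genes = 20, n_cci_specific_genes = 0,
    n_rap_specific_genes = 0, n_d14_signature_genes = 0,
    n_disposition_genes = 0, effect_mean_log2 = 2.0, effect_sd_log2 = 0.3,
    high_var_fraction = 0, seed = 33
  )
  ch <- generate_cohort(cfg)
  tru <- ground_truth_set(ch, "CCI_day1_vs_control")
  v <- ch$expression$values
  grp <- sample_group(ch$metadata)
  diff <- rowMeans(v[tru$gene_id, grp == "CCI_day1", drop = FALSE]) -
    rowMeans(v[tru$gene_id, grp == "control", drop = FALSE])
  se <- 0.3 * sqrt(1 / 500 + 1 / 200)
  expect_true(all(abs(diff - tru$sign * tru$effect_log2) < 4 * se))
  # the average planted magnitude itself is centred on effect_mean_log2
  expect_lt(abs(mean(abs(diff)) - 2.0), 3 * (0.3 / sqrt(20) + se))
})

test_that("cohort configurations load from YAML and JSON files", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_genes: 2000", "n_controls: 6", "seed: 99"), yml)
  cfg <- read_cohort_config(yml)
  expect_equal(cfg$n_genes, 2000L)
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$effect_mean_log2, 2.5) # untouched defaults remain
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_genes": 2000, "n_controls": 6, "seed": 99}', js)
  cfg2 <- read_cohort_config(js)
  expect_identical(generate_cohort(cfg2)$expression$values,
    generate_cohort(cfg)$expression$values)
  writeLines("n_gene: 5", yml)
  expect_error(read_cohort_config(yml), "unknown config field")
})

test_that("a written cohort round-trips through the TSV readers", {
  ch <- generate_cohort(small_config(n_genes = 40, n_controls = 4,
    n_cci_day1 = 3, n_rap_day1 = 3, n_cci_day14 = 4, n_rap_day14 = 4,
    n_shared_storm_genes = 5, n_cci_specific_genes = 2,
    n_rap_specific_genes = 2, n_d14_signature_genes = 3,
    n_disposition_genes = 2
  ))
  dir <- withr::local_tempdir()
  paths <- write_cohort(ch, dir)
  m <- read_expression(paths[["expression"]])
  expect_identical(m$scale, "log2")
  expect_equal(m$values, ch$expression$values, tolerance = 1e-12)
  md <- read_metadata(paths[["metadata"]])
  expect_identical(md$sample_id, ch$metadata$sample_id)
  expect_identical(md$disposition, ch$metadata$disposition)
  tr <- utils::read.delim(paths[["truth"]], stringsAsFactors = FALSE)
  expect_equal(nrow(tr), nrow(ch$truth))
})
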