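de_fixture <- function(seed = 31, g = 25, na = 6, nb = 8) {
  set.seed(seed)
  ids_a <- paste0("a", seq_len(na))
  ids_b <- paste0("b", seq_len(nb))
  m <- toy_matrix(matrix(rnorm(g * (na + nb), mean = 8), g, na + nb),
    samples = c(ids_a, ids_b), scale = "log2"
  )
  list(m = m, meta = two_group_metadata(ids_a, ids_b))
}

test_that("fold changes follow the signed +FC/-FC convention", {
  m <- toy_matrix(rbind(c(5, 5, 4, 4), c(3, 3, 5, 5)),
    samples = c("a1", "a2", "b1", "b2"), scale = "log2"
  )
  meta <- two_group_metadata(c("a1", "a2"), c("b1", "b2"))
  fc <- fold_changes(m, meta, "CCI_day1", "control")
  expect_equal(fc$log2fc, c(1, -2))
  expect_equal(fc$signed_fc, c(2, -4))
  expect_identical(fc$direction, c("up", "down"))
  # antisymmetry under group swap
  rev <- fold_changes(m, meta, "control", "CCI_day1")
  expect_equal(rev$log2fc, -fc$log2fc)
  expect_equal(rev$signed_fc, -fc$signed_fc)
  expect_true(all(abs(fc$signed_fc) >= 1))
})

test_that("the vectorized Welch test agrees with stats::t.test per gene", {
  fx <- de_fixture()
  p <- de_test(fx$m, fx$meta, "CCI_day1", "control")
  ia <- fx$meta$sample_id[fx$meta$cohort == "CCI"]
  ib <- fx$meta$sample_id[fx$meta$cohort == "control"]
  oracle <- apply(fx$m$values, 1, function(row) {
    stats::t.test(row[ia], row[ib], var.equal = FALSE)$p.value
  })
  expect_equal(p, oracle, tolerance = 1e-12)
  expect_error(
    de_test(fx$m, fx$meta, fx$meta$sample_id[1], "control"),
    "at least 2"
  )
})

test_that("copied samples give p = 1 under the degenerate rule", {
  v <- matrix(rep(c(3, 7, 2), 6), nrow = 3)
  m <- toy_matrix(v, samples = paste0("s", 1:6), scale = "log2")
  meta <- two_group_metadata(paste0("s", 1:3), paste0("s", 4:6))
  p <- de_test(m, meta, "CCI_day1", "control")
  expect_true(all(p == 1))
  # zero variance with unequal means is maximal evidence
  v2 <- v
  v2[1, 1:3] <- 9
  m2 <- toy_matrix(v2, samples = paste0("s", 1:6), scale = "log2")
  expect_equal(unname(de_test(m2, meta, "CCI_day1", "control")[1]), 0)
})

test_that("null data give a calibrated type-I error rate", {
  set.seed(32)
  g <- 5000
  m <- toy_matrix(matrix(rnorm(g * 20, 8, 0.5), g, 20),
    samples = paste0("s", 1:20), scale = "log2"
  )
  meta <- two_group_metadata(paste0("s", 1:10), paste0("s", 11:20))
  p <- de_test(m, meta, "CCI_day1", "control")
  frac <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / g)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("planted shifts of the study's magnitude are overwhelmingly detected", {
  set.seed(33)
  g <- 200
  v <- matrix(rnorm(g * 60, 8, 0.3), g, 60)
  v[1:50, 1:20] <- v[1:50, 1:20] + 2.5
  m <- toy_matrix(v, samples = paste0("s", 1:60), scale = "log2")
  meta <- two_group_metadata(paste0("s", 1:20), paste0("s", 21:60))
  p <- de_test(m, meta, "CCI_day1", "control")
  expect_true(all(p[1:50] < 1e-10))
})

test_that("BH adjustment reproduces the worked examples and the oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.049, 0.05)), c(0.015, 0.05, 0.05))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")
  set.seed(34)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-14)
    # monotone: smaller p never gets a larger q
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

test_that("selection is strict at thresholds and monotone in them", {
  rec <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    log2fc = c(1.32, 1, -1.1, 0.1),
    signed_fc = c(2.5, 2.0, -2.14, 1.07),
    p = c(1e-6, 1e-10, 0.0009, 0.001),
    q = c(1e-5, 1e-9, 0.002, 0.01),
    direction = c("up", "up", "down", "up"),
    stringsAsFactors = FALSE
  )
  expect_identical(
    select_genes(rec, de_criteria("fc_and_fdr")), c("g1")
  ) # g2 fails the strict |FC| > 2, g3 fails q
  expect_identical(select_genes(rec, de_criteria("p_only")), c("g1", "g2", "g3"))
  expect_identical(select_genes(rec, de_criteria("fdr_only")), c("g1", "g2"))
  # loosening any threshold never shrinks the set
  set.seed(35)
  recs <- data.frame(
    gene_id = paste0("g", 1:100),
    log2fc = rnorm(100), p = runif(100)^2, stringsAsFactors = FALSE
  )
  recs$signed_fc <- ifelse(recs$log2fc >= 0, 2^recs$log2fc, -2^(-recs$log2fc))
  recs$q <- bh_adjust(recs$p)
  recs$direction <- ifelse(recs$log2fc >= 0, "up", "down")
  for (i in 1:20) {
    th <- sort(runif(2, 0.5, 4))
    qs <- sort(runif(2, 0.001, 0.5))
    tight <- select_genes(recs, de_criteria("fc_and_fdr", fc_threshold = th[2], q_threshold = qs[1]))
    loose <- select_genes(recs, de_criteria("fc_and_fdr", fc_threshold = th[1], q_threshold = qs[2]))
    expect_true(all(tight %in% loose))
  }
  expect_error(de_criteria("p_only", p_threshold = 0), "positive")
})

test_that("concordance counts common genes and their direction agreement", {
  rec <- function(ids, dirs) {
    data.frame(gene_id = ids, direction = dirs, stringsAsFactors = FALSE)
  }
  ra <- rec(c("g1", "g2", "g3"), c("up", "down", "up"))
  rb <- rec(c("g1", "g2", "g3"), c("up", "up", "up"))
  same <- concordance(ra, ra, c("g1", "g2"), c("g1", "g2"))
  expect_equal(same$n_common, 2)
  expect_equal(same$percent_same_direction, 100)
  disj <- concordance(ra, rb, c("g1"), c("g3"))
  expect_equal(disj$n_common, 0)
  expect_true(is.na(disj$percent_same_direction))
  half <- concordance(ra, rb, c("g1", "g2"), c("g1", "g2"))
  expect_equal(half$percent_same_direction, 50)
  expect_error(concordance(ra, rb, "g9", "g9"), "missing gene")
})

test_that("overlap reports a stable sorted intersection", {
  expect_equal(overlap_report(c("g2", "g1"), c("g1", "g2"))$genes, c("g1", "g2"))
  expect_equal(overlap_report(c("g1"), c("g2"))$n_common, 0)
  one <- overlap_report(c("g5", "g3"), c("g3", "g9"))
  expect_identical(one$genes, "g3")
})
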