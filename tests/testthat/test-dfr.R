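test_that("the control reference has unbiased moments and drops flat genes", {
  m <- toy_matrix(rbind(c(0, 2), c(5, 5)), scale = "log2")
  expect_warning(fit_reference(m), "zero-variance")
  ref <- suppressWarnings(fit_reference(m))
  expect_equal(ref$M, 1)
  expect_equal(ref$V, 2)
  expect_identical(ref$dropped, "g2")
  expect_equal(ref$n_controls, 2)
  # permuting control sample order leaves M and V unchanged
  set.seed(11)
  m2 <- toy_matrix(matrix(rnorm(50), 5, 10), scale = "log2")
  ref_a <- fit_reference(m2)
  ref_b <- fit_reference(subset_samples(m2, sample(colnames(m2$values))))
  expect_equal(ref_a$M, ref_b$M)
  expect_equal(ref_a$V, ref_b$V)
  expect_error(
    fit_reference(toy_matrix(matrix(1, 3, 1), scale = "log2")),
    "2 control samples"
  )
  expect_error(
    suppressWarnings(fit_reference(toy_matrix(matrix(1, 3, 4), scale = "log2"))),
    "zero control variance"
  )
})

test_that("DFR reproduces the hand-worked values exactly", {
  ref <- structure(
    list(
      gene_ids = c("g1", "g2", "g3"), M = c(0, 0, 0), V = c(1, 1, 1),
      n_controls = 4, dropped = character(0)
    ),
    class = "dfr_reference"
  )
  # 3 genes, e = (2, 0, 0): sum = 4, DFR = ln 4
  expect_equal(
    dfr_score(c(g1 = 2, g2 = 0, g3 = 0), ref), log(4),
    tolerance = 1e-12
  )
  # each of G genes deviating by exactly sqrt(V): DFR = ln G
  expect_equal(
    dfr_score(c(g1 = 1, g2 = 1, g3 = -1), ref), log(3),
    tolerance = 1e-12
  )
  expect_error(dfr_score(c(g1 = 0, g2 = 0, g3 = 0), ref), "degenerate")
  expect_error(dfr_score(c(g1 = 1, g2 = 1), ref), "missing")
  expect_error(dfr_score(c(1, 1, 1), ref), "named")
})

test_that("DFR is invariant to per-gene rescaling of expression and reference", {
  set.seed(12)
  for (i in 1:100) {
    g <- 20
    M <- rnorm(g)
    V <- rexp(g) + 0.1
    e <- M + rnorm(g)
    ids <- paste0("g", seq_len(g))
    ref <- structure(
      list(gene_ids = ids, M = M, V = V, n_controls = 10, dropped = character(0)),
      class = "dfr_reference"
    )
    base <- dfr_score(stats::setNames(e, ids), ref)
    # rescale one random gene's expression and mean by c, variance by c^2
    k <- sample(g, 1)
    cc <- runif(1, 0.1, 10)
    M2 <- M
    V2 <- V
    e2 <- e
    M2[k] <- cc * M[k]
    e2[k] <- cc * e[k]
    V2[k] <- cc^2 * V[k]
    ref2 <- structure(
      list(gene_ids = ids, M = M2, V = V2, n_controls = 10, dropped = character(0)),
      class = "dfr_reference"
    )
    expect_equal(dfr_score(stats::setNames(e2, ids), ref2), base,
      tolerance = 1e-12
    )
  }
})

test_that("cohort scoring is consistent, order-free and strictly monotone", {
  set.seed(13)
  ctrl <- toy_matrix(matrix(rnorm(200), 20, 10), scale = "log2")
  ref <- fit_reference(ctrl)
  v <- matrix(rnorm(60), 20, 3)
  v[, 2] <- v[, 1] # two identical samples
  m <- toy_matrix(v, samples = c("p1", "p2", "p3"), scale = "log2")
  sc <- dfr_cohort(m, ref)
  expect_equal(sc[["p1"]], sc[["p2"]])
  # single-sample cohort equals dfr_score
  one <- subset_samples(m, "p3")
  expect_equal(
    unname(dfr_cohort(one, ref)),
    dfr_score(m$values[, "p3"], ref)
  )
  # enlarging one gene's deviation strictly increases the score
  v2 <- m$values
  k <- which.max(abs(v2[, 3] - ref$M)) # move further from the reference mean
  v2[k, 3] <- v2[k, 3] + sign(v2[k, 3] - ref$M[k]) * 2
  m2 <- toy_matrix(v2, samples = colnames(v2), scale = "log2")
  expect_gt(dfr_cohort(m2, ref)[["p3"]], sc[["p3"]])
})

test_that("in-sample control scores satisfy the G*(n-1) identity", {
  set.seed(14)
  for (rep in 1:5) {
    g <- sample(50:300, 1)
    n <- sample(5:40, 1)
    ctrl <- toy_matrix(matrix(rnorm(g * n, sd = runif(1, 0.2, 3)), g, n),
      scale = "log2"
    )
    sc <- dfr_control_scores(ctrl, method = "in_sample")
    expect_equal(sum(exp(sc)), g * (n - 1), tolerance = 1e-8)
  }
})

test_that("leave-one-out control scores exceed the in-sample scores on average", {
  set.seed(15)
  ctrl <- toy_matrix(matrix(rnorm(100 * 15), 100, 15), scale = "log2")
  in_s <- dfr_control_scores(ctrl, "in_sample")
  loo <- dfr_control_scores(ctrl, "leave_one_out")
  expect_identical(names(in_s), names(loo))
  expect_gt(mean(loo), mean(in_s))
})

test_that("group summaries gate the test on normality and report the gap", {
  set.seed(16)
  meta <- data.frame(
    sample_id = paste0("s", 1:40),
    cohort = rep(c("CCI", "RAP"), each = 20),
    timepoint = "day1", disposition = NA_character_,
    stringsAsFactors = FALSE
  )
  # group B shifted by 3 ln units: p must be far below 0.001
  sc <- stats::setNames(c(rnorm(20, 10, 0.5), rnorm(20, 13, 0.5)), meta$sample_id)
  gs <- summarize_groups(sc, meta)
  expect_equal(sort(gs$summary$group), c("CCI_day1", "RAP_day1"))
  expect_equal(gs$summary$n, c(20, 20))
  expect_lt(gs$comparisons$p, 1e-3)
  expect_true(gs$comparisons$test %in% c("t-test", "Mann-Whitney"))
  # identically distributed groups: p roughly uniform over replicates
  ps <- replicate(200, {
    x <- stats::setNames(rnorm(40, 10, 1), meta$sample_id)
    summarize_groups(x, meta)$comparisons$p
  })
  expect_lt(abs(mean(ps) - 0.5), 0.06) # 3 x SE of a uniform mean at n = 200
})

test_that("groups smaller than 3 are summarized but not compared", {
  meta <- data.frame(
    sample_id = paste0("s", 1:7),
    cohort = c(rep("CCI", 2), rep("control", 5)),
    timepoint = c(rep("day1", 2), rep("none", 5)),
    disposition = NA_character_, stringsAsFactors = FALSE
  )
  sc <- stats::setNames(c(5, 6, 1, 2, 1.5, 1.2, 1.8), meta$sample_id)
  expect_warning(summarize_groups(sc, meta), "smaller than 3")
  gs <- suppressWarnings(summarize_groups(sc, meta))
  expect_equal(nrow(gs$summary), 2)
  expect_identical(gs$comparisons$test, "skipped")
  expect_true(is.na(gs$comparisons$p))
})
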