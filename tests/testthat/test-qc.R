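make_cohort <- function(x, labels, batch, scale = "raw") {
  n <- nrow(x); p <- ncol(x)
  colnames(x) <- sprintf("met_%02d", seq_len(p))
  rownames(x) <- sprintf("S%03d", seq_len(n))
  metabnet:::new_cohort(
    tibble::tibble(sample_id = rownames(x), label = labels, batch = batch),
    x,
    tibble::tibble(metabolite = colnames(x), super_pathway = "Lipid",
                   sub_pathway = "Sub", hmdb_id = "", xenobiotic = FALSE),
    scale = scale
  )
}

test_that("batch merge rescales by the ratio of control medians", {
  x <- rbind(matrix(10, 6, 2), matrix(5, 6, 2))
  coh <- make_cohort(x, labels = rep(0L, 12), batch = rep(c("B1", "B2"), each = 6))
  out <- merge_batches(coh)
  expect_equal(unname(out$cohort$intensities[7:12, 1]), rep(10, 6))
  f <- out$report$scale_factor[[1]]
  expect_equal(unname(f["B2"]), 2)
  expect_equal(unname(f["B1"]), 1)
  # reference batch rows are bit-identical
  expect_identical(out$cohort$intensities[1:6, ], coh$intensities[1:6, ])
})

test_that("planted batch factors are recovered from control medians", {
  sim <- generate_cohort(small_config(seed = 21, n_cases = 100,
                                      n_controls = 2400, missing_rate = 0,
                                      batch_sdlog = 0.3, n_constant = 0,
                                      n_metabolites = 30, n_skewed = 0))
  out <- merge_batches(sim$cohort)
  est <- vapply(out$report$scale_factor, function(f) unname(f["B2"]), 0)
  true <- 1 / sim$truth$batch_factors[, "B2"]
  expect_lt(stats::median(abs(est / true - 1)), 0.1)
  expect_gt(mean(abs(est / true - 1) < 0.1), 0.8)
})

test_that("batch merge demands controls in every batch", {
  x <- matrix(runif(20, 1, 2), 10, 2)
  coh <- make_cohort(x, labels = c(rep(0L, 5), rep(1L, 5)),
                     batch = rep(c("B1", "B2"), each = 5))
  expect_error(merge_batches(coh), "no control",
               class = "metabnet_batch_error")
})

test_that("the QC filter applies its rules in order, inclusively at 50%", {
  set.seed(31)
  n <- 40
  batch <- rep(c("B1", "B2"), each = n / 2)
  good <- exp(rnorm(n, 7))
  half_missing_b1 <- good
  half_missing_b1[seq_len(n / 2)[1:(n / 4)]] <- NA # exactly 50% of batch 1
  constant <- rep(3, n)
  skewed <- exp(rlnorm(n)) # lognormal log-values, skewness far above 2
  x <- cbind(good, half_missing_b1, constant, skewed)
  coh <- make_cohort(x, labels = rep(0:1, n / 2), batch = batch)
  out <- qc_filter(coh)
  expect_equal(out$report$status,
               c("kept", "dropped_missingness", "dropped_iqr0", "dropped_skew"))
  expect_equal(colnames(out$cohort$intensities), "met_01")
  expect_equal(out$cohort$scale, "log")
  expect_equal(unname(out$cohort$intensities[, 1]), log(good))
  expect_equal(attr(out$report, "n_before"), 4)
  expect_equal(attr(out$report, "n_after"), 1)
})

test_that("the skewness estimator matches the bias-corrected reference", {
  skip_if_not_installed("e1071")
  set.seed(32)
  for (v in list(rnorm(50), rlnorm(80), rexp(30))) {
    expect_equal(sample_skewness(v), e1071::skewness(v, type = 2),
                 tolerance = 1e-12)
  }
})

test_that("a symmetric Gaussian column is kept while heavy tails are dropped", {
  set.seed(33)
  n <- 200
  x <- cbind(exp(rnorm(n, 6)), exp(rlnorm(n, 0, 1) + 5))
  coh <- make_cohort(x, labels = rep(0:1, n / 2), batch = rep("B1", n))
  out <- qc_filter(coh)
  expect_equal(out$report$status, c("kept", "dropped_skew"))
})

test_that("the QC filter is idempotent", {
  sim <- generate_cohort(small_config(seed = 34))
  once <- qc_filter(merge_batches(sim$cohort)$cohort)
  twice <- qc_filter(once$cohort)
  expect_identical(twice$cohort$intensities, once$cohort$intensities)
  expect_true(all(twice$report$status == "kept"))
})

test_that("an empty panel is an explicit error", {
  x <- matrix(1, 10, 2) # both constant
  coh <- make_cohort(x, labels = rep(0:1, 5), batch = rep("B1", 10))
  expect_error(qc_filter(coh), class = "metabnet_empty_panel_error")
})

test_that("half-minimum imputation fills left-censored values from below", {
  x <- matrix(c(4, 8, NA, 1, 2, 3), ncol = 2)
  coh <- make_cohort(log(x), labels = c(0L, 1L, 0L), batch = rep("B1", 3),
                     scale = "log")
  out <- impute_missing(coh)
  expect_equal(unname(out$intensities[3, 1]), log(2)) # half of minimum 4
  # no missing values -> identity
  coh2 <- make_cohort(log(x[, 2, drop = FALSE]), labels = c(0L, 1L, 0L),
                      batch = rep("B1", 3), scale = "log")
  expect_identical(impute_missing(coh2)$intensities, coh2$intensities)
  # imputed values never exceed observed values per metabolite
  sw <- small_xy(seed = 35, missing_rate = 0.15)
  expect_true(all(!is.na(sw$x)))
})

test_that("imputation refuses raw-scale and all-missing input", {
  x <- matrix(c(1, 2, NA, NA), 2, 2)
  coh <- make_cohort(x, labels = 0:1, batch = rep("B1", 2))
  expect_error(impute_missing(coh), class = "metabnet_scale_error")
  coh$scale <- "log"
  expect_error(impute_missing(coh), class = "metabnet_impute_error")
})

test_that("bootstrap balancing doubles the majority class exactly", {
  bal <- bootstrap_balance(c(rep(1, 59), rep(0, 352)), seed = 3)
  expect_equal(nrow(bal), 704)
  expect_equal(sum(bal$label == 1), 352)
  expect_equal(sum(bal$label == 0), 352)
  # every majority (control) row appears exactly once
  expect_equal(sort(bal$index[bal$label == 0]), 60:411)
  # minority draws come from the cases, with replacement
  expect_true(all(bal$index[bal$label == 1] %in% 1:59))
})

test_that("already balanced labels keep each majority row once", {
  bal <- bootstrap_balance(rep(0:1, each = 10), seed = 1)
  expect_equal(nrow(bal), 20)
  expect_setequal(bal$index[bal$label == 0], 1:10)
})

test_that("resampling contract holds exhaustively at tiny n", {
  labs <- c(1, 0, 0, 0, 0, 0)
  ok <- vapply(1:500, function(s) {
    bal <- bootstrap_balance(labs, seed = s)
    nrow(bal) == 10 &&
      identical(sort(bal$index[bal$label == 0]), 2:6) &&
      all(bal$index[bal$label == 1] == 1)
  }, TRUE)
  expect_true(all(ok))
  expect_error(bootstrap_balance(rep(1, 5)), class = "metabnet_balance_error")
})

test_that("standardization is exact, reusable and invertible", {
  set.seed(41)
  x <- matrix(rnorm(60, 5, 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  st <- standardize(x)
  expect_equal(unname(colMeans(st$x)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(st$x, 2, sd)), rep(1, 3), tolerance = 1e-12)
  again <- standardize(x, centers = st$centers, scales = st$scales)
  expect_identical(again$x, st$x)
  back <- sweep(sweep(st$x, 2, st$scales, "*"), 2, st$centers, "+")
  expect_equal(back, x, tolerance = 1e-12)
  x[, 2] <- 1
  expect_error(standardize(x), "b", class = "metabnet_scale_error")
})
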