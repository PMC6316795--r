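test_that("cohorts are bit-identical under the same configuration and seed", {
  a <- generate_cohort(small_config(seed = 9))
  b <- generate_cohort(small_config(seed = 9))
  expect_identical(a$cohort$intensities, b$cohort$intensities)
  expect_identical(a$cohort$samples, b$cohort$samples)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(small_config(seed = 10))
  expect_false(identical(a$cohort$intensities, c$cohort$intensities))
})

test_that("study-scale shapes and basic invariants hold", {
  sim <- generate_cohort(synthetic_config(n_cases = 59, n_controls = 352,
                                          n_metabolites = 481, seed = 2))
  expect_equal(dim(sim$cohort$intensities), c(411, 481))
  expect_equal(sum(sim$cohort$samples$label), 59)
  expect_equal(nrow(sim$cohort$annotations), 481)
  obs <- sim$cohort$intensities[!is.na(sim$cohort$intensities)]
  expect_true(all(obs > 0))
  expect_true(all(table(sim$cohort$samples$batch,
                        sim$cohort$samples$label) > 0))
})

test_that("configuration errors name the offending field", {
  expect_error(synthetic_config(n_cases = -1), "n_cases",
               class = "metabnet_config_error")
  expect_error(synthetic_config(missing_rate = 1), "missing_rate",
               class = "metabnet_config_error")
  expect_error(synthetic_config(n_metabolites = 10, n_signal = 5,
                                n_skewed = 5, n_constant = 5),
               class = "metabnet_config_error")
})

test_that("null cohorts carry no phenotype signal (planted-null calibration)", {
  pvals <- c()
  for (s in 1:4) {
    sim <- generate_cohort(small_config(seed = s, effect_size = 0,
                                        missing_rate = 0, n_signal = 5,
                                        n_coparent_pairs = 2, n_constant = 0,
                                        n_skewed = 0, n_metabolites = 60,
                                        block_rho = 0))
    lx <- log(sim$cohort$intensities)
    y <- sim$cohort$samples$label
    pvals <- c(pvals, apply(lx, 2, function(v) t.test(v[y == 1], v[y == 0])$p.value))
  }
  frac <- mean(pvals < 0.05)
  # binomial error around 0.05 over 240 metabolite tests
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(pvals)) + 0.01)
})

test_that("skewed columns exceed |skewness| 2 and constants have zero IQR", {
  sim <- generate_cohort(small_config(seed = 4, missing_rate = 0,
                                      n_skewed = 6, n_constant = 3,
                                      n_cases = 60, n_controls = 180,
                                      n_batches = 1))
  lx <- log(sim$cohort$intensities)
  skw <- apply(lx[, sim$truth$skewed, drop = FALSE], 2, sample_skewness)
  expect_true(all(abs(skw) > 2))
  iqr <- apply(lx[, sim$truth$constant, drop = FALSE], 2,
               function(v) diff(quantile(v, c(0.25, 0.75))))
  expect_true(all(iqr == 0))
})

test_that("left-censoring removes roughly the requested fraction, from below", {
  sim <- generate_cohort(small_config(seed = 5, missing_rate = 0.2,
                                      n_constant = 0))
  x <- sim$cohort$intensities
  miss <- colMeans(is.na(x))
  expect_true(all(abs(miss - 0.2) < 0.05))
  # censored entries sit below every observed value of their metabolite
  raw <- generate_cohort(small_config(seed = 5, missing_rate = 0,
                                      n_constant = 0))$cohort$intensities
  for (j in sample(ncol(x), 10)) {
    cens <- is.na(x[, j])
    if (any(cens)) expect_lt(max(raw[cens, j]), min(raw[!cens, j]))
  }
})

test_that("oracle scores reduce to the class prior without signal and obey symmetry", {
  sim <- generate_cohort(small_config(seed = 6, n_signal = 0,
                                      n_coparent_pairs = 0, missing_rate = 0))
  sc <- oracle_scores(sim$cohort, sim$truth)
  expect_equal(sc, rep(sim$truth$class_prior, nrow(sim$cohort$intensities)),
               tolerance = 1e-12)

  # single signal metabolite with symmetric means: x at the midpoint -> 0.5
  sim2 <- generate_cohort(small_config(seed = 7, n_signal = 1,
                                       n_coparent_pairs = 0,
                                       n_cases = 50, n_controls = 50,
                                       missing_rate = 0, n_batches = 1,
                                       effect_size = 1))
  tr <- sim2$truth
  j <- tr$signal$index[1]
  mid <- (tr$signal$mean_case[1] + tr$signal$mean_control[1]) / 2
  coh <- sim2$cohort
  coh$intensities[1, j] <- exp(mid)
  sc2 <- oracle_scores(coh, tr)
  expect_equal(sc2[1], 0.5, tolerance = 1e-12)
})

test_that("oracle posterior matches numeric integration over the latent pair factor", {
  # co-parent pairs are generated as A = U + eA, B = -U + eB + delta y with
  # U latent; integrating U out numerically gives the pair's joint density
  # independently of the closed bivariate-normal form used by the oracle
  sim <- generate_cohort(small_config(seed = 8, n_signal = 1,
                                      n_coparent_pairs = 1, missing_rate = 0,
                                      n_batches = 1))
  tr <- sim$truth
  coh <- sim$cohort
  sc <- oracle_scores(coh, tr)
  lx <- log(coh$intensities)
  cp <- tr$coparents
  sg <- tr$signal
  pair_dens <- function(a, b, y) {
    f <- function(u) {
      dnorm(u, 0, cp$u_sd) * dnorm(a - cp$mean_a - u, 0, cp$e_sd) *
        dnorm(b - cp$mean_b + u - cp$delta * y, 0, cp$e_sd)
    }
    integrate(f, -8 * cp$u_sd, 8 * cp$u_sd, rel.tol = 1e-12)$value
  }
  for (i in c(1, 17, 42)) {
    a <- lx[i, cp$index_a]; b <- lx[i, cp$index_b]; x <- lx[i, sg$index]
    l1 <- log(tr$class_prior) + log(pair_dens(a, b, 1)) +
      dnorm(x, sg$mean_case, sqrt(sg$var_case), log = TRUE)
    l0 <- log(1 - tr$class_prior) + log(pair_dens(a, b, 0)) +
      dnorm(x, sg$mean_control, sqrt(sg$var_control), log = TRUE)
    expect_equal(sc[i], 1 / (1 + exp(l0 - l1)), tolerance = 1e-8)
  }
})

test_that("empirical oracle AUC agrees with the closed-form Bayes AUC", {
  cfg <- small_config(seed = 11, n_cases = 200, n_controls = 200,
                      n_metabolites = 60, n_signal = 5, effect_size = 2,
                      n_coparent_pairs = 0, missing_rate = 0)
  sim <- generate_cohort(cfg)
  sc <- oracle_scores(sim$cohort, sim$truth)
  emp <- aucch(roc_curve(sc, sim$cohort$samples$label))$auc
  expect_equal(emp, oracle_auc(sim$truth), tolerance = 0.03)
})

test_that("cohorts round-trip through the plain-text writers", {
  sim <- generate_cohort(small_config(seed = 12))
  dir <- withr::local_tempdir()
  write_cohort(sim$cohort, dir, truth = sim$truth)
  expect_true(all(file.exists(file.path(dir, c("intensities.tsv",
                                               "annotations.tsv",
                                               "samples.csv", "truth.json")))))
  back <- read_cohort(dir)
  expect_equal(back$intensities, sim$cohort$intensities, tolerance = 1e-12)
  expect_equal(back$annotations, sim$cohort$annotations)
  expect_equal(as.data.frame(back$samples), as.data.frame(sim$cohort$samples),
               tolerance = 1e-12)
})

test_that("mismatched truth is rejected", {
  sim <- generate_cohort(small_config(seed = 13))
  other <- generate_cohort(small_config(seed = 13, n_metabolites = 20))
  expect_error(oracle_scores(sim$cohort, other$truth),
               class = "metabnet_dims_error")
})
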