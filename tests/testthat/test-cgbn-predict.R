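fit_small_net <- function(n = 500, seed = 91, bf = 8) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  a <- rnorm(n) + 1.1 * y
  b <- 0.8 * a + rnorm(n, 0, 0.7)
  c0 <- rnorm(n)
  d <- 0.9 * c0 + 0.7 * y + rnorm(n, 0, 0.6)
  x <- cbind(a = a, b = b, c0 = c0, d = d)
  list(net = fit_cgbn(x, y, bf_threshold = bf), x = x, y = y)
}

test_that("posterior-mean parameters approach least squares as nu -> 0", {
  set.seed(92)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  child <- 1.5 + 2 * x1 - x2 + rnorm(n)
  d <- data.frame(child = child, x1 = x1, x2 = x2)
  paths <- list(x1 = list(parent = character(0), log_bf = numeric(0)),
                x2 = list(parent = character(0), log_bf = numeric(0)),
                child = list(parent = c("x1", "x2"), log_bf = c(50, 50)))
  net <- metabnet:::new_cgbn_network(c("x1", "x2", "child"),
                                     rep("gaussian", 3), paths,
                                     bf_threshold = 8,
                                     priors = cgbn_priors(nu = 1e-8),
                                     max_parents = 2, phenotype = NULL,
                                     discrete = character())
  net <- fit_parameters(net, d, cgbn_priors(nu = 1e-8))
  ols <- unname(stats::coef(stats::lm(child ~ x1 + x2, d)))
  got <- net$params$child$coefficients[1, ]
  expect_lt(max(abs(got - ols)), 1e-6)
})

test_that("a parentless Gaussian node gets the nu-shrunk sample mean", {
  set.seed(93)
  v <- rnorm(40, 3)
  d <- data.frame(m = v)
  paths <- list(m = list(parent = character(0), log_bf = numeric(0)))
  net <- metabnet:::new_cgbn_network("m", "gaussian", paths, 8, cgbn_priors(),
                                     2, NULL, character())
  net <- fit_parameters(net, d)
  expect_equal(net$params$m$coefficients[1, 1],
               length(v) * mean(v) / (length(v) + 10), tolerance = 1e-12)
})

test_that("class-conditional intercepts are symmetric for symmetric data", {
  set.seed(94)
  n <- 2000
  y <- rep(0:1, each = n / 2)
  x <- cbind(m = rnorm(n) + ifelse(y == 1, 0.8, -0.8))
  net <- fit_cgbn(x, y, bf_threshold = 2)
  p <- net$params$m
  expect_equal(p$disc_parents, "phenotype")
  ints <- p$coefficients[, 1]
  expect_lt(abs(sum(ints)), 4 / sqrt(n)) # symmetric about 0 within SE
})

test_that("an empty neighborhood predicts the smoothed class prior exactly", {
  set.seed(95)
  n <- 120
  y <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("m", 1:5)))
  net <- fit_cgbn(x, y, bf_threshold = Inf)
  sc <- predict_cgbn(net, x)
  A <- net$priors$dirichlet_alpha
  expect_equal(sc, rep((n / 2 + A / 2) / (n + A), n), tolerance = 1e-12)
})

test_that("a symmetric single-child observation at zero scores one half", {
  set.seed(96)
  n <- 5000
  y <- rep(0:1, each = n / 2)
  x <- cbind(m = rnorm(n) + ifelse(y == 1, 1, -1))
  net <- fit_cgbn(x, y, bf_threshold = 2)
  # overwrite with exactly symmetric parameters to isolate the symmetry law
  net$params$m$coefficients[, 1] <- c(-1, 1)
  net$params$m$variance[] <- 1
  net$params$phenotype$cpt[] <- c(0.5, 0.5)
  mid <- matrix(net$centers, 1, dimnames = list(NULL, "m")) # standardized 0
  expect_equal(predict_cgbn(net, mid), 0.5, tolerance = 1e-12)
})

test_that("prediction matches brute-force joint evaluation on small networks", {
  fs <- fit_small_net()
  sc <- predict_cgbn(fs$net, fs$x)
  df <- fs$net$train_data
  lv <- levels(df$phenotype)
  nodes <- setdiff(fs$net$nodes$name, "phenotype")
  brute_one <- function(row) {
    lp <- vapply(lv, function(v) {
      ll <- log(metabnet:::cpt_lookup(fs$net$params$phenotype, row,
                                      clamp = c(phenotype = v))[1, v])
      for (nd in nodes) {
        ll <- ll + metabnet:::gaussian_node_logdens(
          fs$net$params[[nd]], row, clamp = c(phenotype = v), row[[nd]])
      }
      ll
    }, 0)
    1 / (1 + exp(lp[1] - lp[2]))
  }
  idx <- c(2, 10, 101, 350)
  expect_equal(vapply(idx, function(i) brute_one(df[i, , drop = FALSE]), 0),
               sc[idx], tolerance = 1e-6)
})

test_that("nodes outside the Markov neighborhood cannot affect prediction", {
  fs <- fit_small_net()
  mn <- markov_neighborhood(fs$net)
  outside <- setdiff(colnames(fs$x), mn$node)
  skip_if(length(outside) == 0, "all nodes in the neighborhood for this fit")
  x2 <- fs$x
  x2[, outside] <- matrix(rnorm(length(outside) * nrow(x2)), nrow(x2))
  expect_identical(predict_cgbn(fs$net, fs$x), predict_cgbn(fs$net, x2))
})

test_that("missing neighborhood metabolites are reported by name", {
  fs <- fit_small_net()
  mn <- markov_neighborhood(fs$net)
  x2 <- fs$x
  x2[3, mn$node[1]] <- NA
  expect_error(predict_cgbn(fs$net, x2), mn$node[1],
               class = "metabnet_columns_error")
})

test_that("an unsampled discrete-parent configuration falls back to the prior", {
  set.seed(97)
  n <- 100
  y <- rep(0:1, each = n / 2)
  x <- cbind(m = rnorm(n) + y)
  net <- fit_cgbn(x, y, bf_threshold = 2,
                  covariates = data.frame(g = rep("only_level", n)))
  # force a two-level factor with one unseen level into the training frame
  df <- net$train_data
  df$g <- factor(as.character(df$g), levels = c("only_level", "ghost"))
  net2 <- metabnet:::new_cgbn_network(
    net$ordering, net$nodes$type,
    list(phenotype = list(parent = character(0), log_bf = numeric(0)),
         g = list(parent = character(0), log_bf = numeric(0)),
         m = list(parent = c("phenotype", "g"), log_bf = c(20, 20))),
    bf_threshold = 8, priors = net$priors, max_parents = 2,
    phenotype = "phenotype", discrete = c("phenotype", "g"))
  net2 <- fit_parameters(net2, df)
  p <- net2$params$m
  ghost_rows <- p$configs$g == "ghost"
  pr <- net$priors
  expect_true(all(p$coefficients[ghost_rows, 1] == 0))
  expect_true(all(p$variance[ghost_rows] ==
                    (pr$alpha * pr$sigma2 / 2) / (pr$alpha / 2 - 1)))
})

test_that("network tidiers summarise edges and neighborhood size", {
  fs <- fit_small_net()
  td <- tidy(fs$net)
  expect_named(td, c("from", "to", "log_bf"))
  gl <- glance(fs$net)
  expect_equal(gl$n_edges, nrow(fs$net$edges))
  expect_equal(gl$markov_neighborhood_size, nrow(markov_neighborhood(fs$net)))
})
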