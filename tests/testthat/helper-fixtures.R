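# Small deterministic fixtures shared across test files.

small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_cases = 25, n_controls = 75, n_metabolites = 50, n_signal = 5,
         effect_size = 1, n_coparent_pairs = 2, block_size = 5,
         block_rho = 0.4, missing_rate = 0.03, n_constant = 2, n_skewed = 4,
         seed = seed),
    list(...)
  )
  do.call(synthetic_config, args)
}

# Complete log-scale matrix + labels, the shape most model tests need.
small_xy <- function(seed = 1, ...) {
  sim <- generate_cohort(small_config(seed, ...))
  m <- merge_batches(sim$cohort)
  f <- qc_filter(m$cohort)
  d <- impute_missing(f$cohort)
  list(x = d$intensities, labels = d$samples$label, truth = sim$truth,
       cohort = sim$cohort)
}

# The published 3x2 race contingency table (controls, cases).
race_counts <- matrix(c(119, 159, 74, 15, 40, 4), ncol = 2,
                      dimnames = list(c("White", "Black", "Other"),
                                      c("control", "case")))

expect_setequal_edges <- function(net, expected) {
  got <- sort(paste0(net$edges$from, "->", net$edges$to))
  expect_identical(got, sort(expected))
}
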