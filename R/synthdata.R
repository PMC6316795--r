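#' Configuration for a synthetic metabolomics cohort
#'
#' Describes a case/control plasma metabolomics study to simulate. The
#' defaults emulate a two-batch untargeted Metabolon-style panel measured on
#' 411 children (59 asthma cases, 352 controls) with 481 named metabolites,
#' of which a QC pipeline is expected to retain roughly 433: a planted set of
#' metabolites whose log-intensities are conditionally Gaussian on case
#' status, co-parent pairs that are jointly (but not marginally) informative,
#' equicorrelated noise blocks, per-metabolite multiplicative batch factors,
#' left-censored below-detection missingness, and a handful of constant and
#' heavily skewed metabolites that QC should remove.
#'
#' @param n_cases,n_controls Number of case and control samples.
#' @param n_metabolites Total number of metabolite columns.
#' @param n_signal Number of metabolites directly dependent on the phenotype.
#' @param effect_size Mean shift between classes, in units of the
#'   log-intensity standard deviation, for each signal metabolite (and for
#'   the sum of each co-parent pair).
#' @param n_coparent_pairs Number of planted metabolite pairs in which the
#'   phenotype shifts the pair's sum but neither member strongly alone.
#' @param block_size,block_rho Size and equicorrelation of correlated noise
#'   blocks (`block_rho` in `[0, 1)`).
#' @param n_batches Number of processing batches. With the default of 2 the
#'   batch sizes follow the 245/166 split of the motivating study; otherwise
#'   batches are equal-sized.
#' @param batch_sdlog Log-scale spread of the per-metabolite multiplicative
#'   batch factors (batch 1 is the reference and has factor 1).
#' @param missing_rate Fraction of each metabolite's values censored as
#'   below-detection (values under the per-metabolite quantile are removed).
#' @param n_constant Number of constant (zero-IQR) metabolites.
#' @param n_skewed Number of metabolites whose log-intensities are drawn from
#'   a heavy-tailed distribution with |skewness| > 2.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n_cases = 59, n_controls = 352,
                             n_metabolites = 481, n_signal = 15,
                             effect_size = 0.4, n_coparent_pairs = 5,
                             block_size = 10, block_rho = 0.5,
                             n_batches = 2, batch_sdlog = 0.2,
                             missing_rate = 0.05, n_constant = 8,
                             n_skewed = 40, seed = 1L) {
  cfg <- list(
    n_cases = n_cases, n_controls = n_controls,
    n_metabolites = n_metabolites, n_signal = n_signal,
    effect_size = effect_size, n_coparent_pairs = n_coparent_pairs,
    block_size = block_size, block_rho = block_rho,
    n_batches = n_batches, batch_sdlog = batch_sdlog,
    missing_rate = missing_rate, n_constant = n_constant,
    n_skewed = n_skewed, seed = as.integer(seed)
  )
  counts <- c("n_cases", "n_controls", "n_metabolites", "n_signal",
              "n_coparent_pairs", "block_size", "n_batches",
              "n_constant", "n_skewed")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1 || !is.finite(v) || v < 0 || v != round(v)) {
      abort(sprintf("invalid configuration: `%s` must be a non-negative integer", f),
            class = "metabnet_config_error")
    }
  }
  for (f in c("missing_rate", "block_rho")) {
    v <- cfg[[f]]
    if (length(v) != 1 || !is.finite(v) || v < 0 || v >= 1) {
      abort(sprintf("invalid configuration: `%s` must lie in [0, 1)", f),
            class = "metabnet_config_error")
    }
  }
  if (!is.finite(cfg$effect_size)) {
    abort("invalid configuration: `effect_size` must be finite",
          class = "metabnet_config_error")
  }
  if (cfg$batch_sdlog < 0 || !is.finite(cfg$batch_sdlog)) {
    abort("invalid configuration: `batch_sdlog` must be non-negative",
          class = "metabnet_config_error")
  }
  used <- cfg$n_signal + 2 * cfg$n_coparent_pairs + cfg$n_constant + cfg$n_skewed
  if (used > cfg$n_metabolites) {
    abort(paste0("invalid configuration: n_signal + 2*n_coparent_pairs + ",
                 "n_constant + n_skewed exceeds n_metabolites"),
          class = "metabnet_config_error")
  }
  if (cfg$n_batches >= 1 && cfg$n_cases + cfg$n_controls > 0 &&
      cfg$n_batches > cfg$n_cases + cfg$n_controls) {
    abort("invalid configuration: `n_batches` exceeds the number of samples",
          class = "metabnet_config_error")
  }
  structure(cfg, class = "synthetic_config")
}

# Internal constructor shared by the generator and the readers.
new_cohort <- function(samples, intensities, annotations, scale = "raw") {
  stopifnot(nrow(intensities) == nrow(samples),
            ncol(intensities) == nrow(annotations))
  structure(list(samples = samples, intensities = intensities,
                 annotations = annotations, scale = scale),
            class = "metab_cohort")
}

#' @export
print.metab_cohort <- function(x, ...) {
  cat(sprintf("<metab_cohort> %d samples x %d metabolites (%s scale)\n",
              nrow(x$intensities), ncol(x$intensities), x$scale))
  cat(sprintf("  cases: %d  controls: %d  batches: %s  missing: %.1f%%\n",
              sum(x$samples$label == 1), sum(x$samples$label == 0),
              paste(names(table(x$samples$batch)), collapse = "/"),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Generate a synthetic metabolomics cohort with known ground truth
#'
#' Simulates a case/control cohort under a conditional-Gaussian generating
#' model on the natural-log intensity scale. Signal metabolites receive a
#' class-dependent mean; each co-parent pair `(A, B)` shares a large latent
#' component with opposite signs so that the phenotype shifts `A + B`
#' strongly while each member alone is only weakly informative; remaining
#' noise metabolites are organised into equicorrelated blocks. Log values are
#' exponentiated, per-metabolite multiplicative batch factors are applied,
#' values below each metabolite's detection quantile are censored to `NA`,
#' and designated columns are made constant or heavily skewed.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `cohort` (a `metab_cohort`: samples tibble,
#'   raw intensity matrix, annotations tibble) and `truth` (a
#'   `ground_truth`: planted class means/variances, co-parent structure,
#'   batch factor matrix, and class prior).
#' @examples
#' sim <- generate_cohort(synthetic_config(n_cases = 10, n_controls = 30,
#'                                         n_metabolites = 40, seed = 7))
#' sim$cohort
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  p <- config$n_metabolites
  label <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
  label <- sample(label)
  ids <- sprintf("S%04d", seq_len(n))
  met <- sprintf("met_%04d", seq_len(p))

  # assign roles to shuffled column positions
  pool <- sample.int(p)
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- head(pool, k)
    pool <<- pool[-seq_len(min(k, length(pool)))]
    out
  }
  idx_signal <- sort(take(config$n_signal))
  idx_pair_a <- take(config$n_coparent_pairs)
  idx_pair_b <- take(config$n_coparent_pairs)
  idx_const <- sort(take(config$n_constant))
  idx_skew <- sort(take(config$n_skewed))
  idx_noise <- sort(pool)

  mu <- runif(p, 5, 9) # baseline log-intensity per metabolite
  logx <- matrix(rnorm(n * p), n, p)

  sgn <- sample(c(-1, 1), max(config$n_signal, 1), replace = TRUE)
  for (j in seq_along(idx_signal)) {
    shift <- sgn[j] * config$effect_size
    logx[, idx_signal[j]] <- logx[, idx_signal[j]] + shift * label
  }

  u_sd <- 2; e_sd <- 0.5
  delta <- config$effect_size * sqrt(2) * e_sd # shifts the sum by effect_size SDs
  for (j in seq_along(idx_pair_a)) {
    u <- rnorm(n, 0, u_sd)
    logx[, idx_pair_a[j]] <- u + rnorm(n, 0, e_sd)
    logx[, idx_pair_b[j]] <- -u + rnorm(n, 0, e_sd) + delta * label
  }

  if (length(idx_noise) > 0 && config$block_size > 1 && config$block_rho > 0) {
    blocks <- split(idx_noise,
                    ceiling(seq_along(idx_noise) / config$block_size))
    for (b in blocks) {
      z <- rnorm(n)
      logx[, b] <- sqrt(config$block_rho) * z +
        sqrt(1 - config$block_rho) * logx[, b]
    }
  }

  if (length(idx_skew) > 0) {
    # lognormal log-intensities: sample skewness ~ 6, well past the |2| QC cut
    logx[, idx_skew] <- matrix(rlnorm(n * length(idx_skew)), n)
  }
  logx <- sweep(logx, 2, mu, "+")
  if (length(idx_const) > 0) logx[, idx_const] <- rep(mu[idx_const], each = n)

  raw <- exp(logx)

  # batches: stratified by class so controls appear in every batch
  if (config$n_batches == 2) {
    prop <- c(245, 166) / 411
  } else {
    prop <- rep(1 / config$n_batches, config$n_batches)
  }
  batch <- integer(n)
  for (cl in c(0L, 1L)) {
    rows <- sample(which(label == cl))
    cuts <- diff(c(0, round(cumsum(prop * length(rows)))))
    batch[rows] <- rep(seq_len(config$n_batches), cuts)
  }
  batch_factors <- matrix(1, p, config$n_batches,
                          dimnames = list(met, paste0("B", seq_len(config$n_batches))))
  if (config$n_batches > 1) {
    batch_factors[, -1] <- rlnorm(p * (config$n_batches - 1),
                                  0, config$batch_sdlog)
  }
  raw <- raw * t(batch_factors[, batch, drop = FALSE])

  if (config$missing_rate > 0) {
    for (j in seq_len(p)) {
      thr <- quantile(raw[, j], config$missing_rate, names = FALSE)
      raw[raw[, j] < thr, j] <- NA_real_
    }
  }
  dimnames(raw) <- list(ids, met)

  samples <- tibble(
    sample_id = ids, label = label, batch = paste0("B", batch),
    race = sample(c("White", "Black", "Other"), n, replace = TRUE,
                  prob = c(0.33, 0.48, 0.19)),
    gender = sample(c("Male", "Female"), n, replace = TRUE),
    treatment = sample(c("Placebo", "Intervention"), n, replace = TRUE),
    bmi = rnorm(n, 16.7, 2.1)
  )
  super <- c("Lipid", "Amino Acid", "Xenobiotics", "Nucleotide", "Peptide",
             "Carbohydrate", "Cofactors and Vitamins", "Energy")
  xeno <- logical(p); xeno[sample.int(p, round(0.12 * p))] <- TRUE
  annotations <- tibble(
    metabolite = met,
    super_pathway = ifelse(xeno, "Xenobiotics",
                           sample(setdiff(super, "Xenobiotics"), p, replace = TRUE)),
    sub_pathway = paste0("Sub pathway ", sample.int(40, p, replace = TRUE)),
    hmdb_id = ifelse(runif(p) < 0.7, sprintf("HMDB%05d", sample.int(99999, p)), ""),
    xenobiotic = xeno
  )

  truth <- structure(list(
    signal = tibble(
      index = idx_signal, metabolite = met[idx_signal],
      mean_control = mu[idx_signal],
      mean_case = mu[idx_signal] + sgn[seq_along(idx_signal)] * config$effect_size,
      var_control = rep(1, length(idx_signal)),
      var_case = rep(1, length(idx_signal))
    ),
    coparents = tibble(
      pair = seq_along(idx_pair_a),
      index_a = idx_pair_a, index_b = idx_pair_b,
      metabolite_a = met[idx_pair_a], metabolite_b = met[idx_pair_b],
      mean_a = mu[idx_pair_a], mean_b = mu[idx_pair_b],
      delta = rep(delta, length(idx_pair_a)),
      u_sd = rep(u_sd, length(idx_pair_a)),
      e_sd = rep(e_sd, length(idx_pair_a))
    ),
    constant = idx_const, skewed = idx_skew,
    batch_factors = batch_factors,
    class_prior = config$n_cases / max(1, n),
    config = config
  ), class = "ground_truth")

  list(cohort = new_cohort(samples, raw, annotations), truth = truth)
}

#' Exact posterior case probability under the generating model
#'
#' Computes, by Bayes' rule, the probability of case status given the
#' observed intensities using the planted class-conditional Gaussian
#' densities of the ground truth (signal metabolites and co-parent pairs;
#' batch factors are divided out on the log scale). This is the
#' Bayes-optimal scorer for the synthetic cohort and serves as the reference
#' against which fitted classifiers are judged. Missing entries simply drop
#' out of the likelihood (for a pair with one member missing, the observed
#' member's exact marginal is used).
#'
#' @param cohort A `metab_cohort` on the raw intensity scale, as produced by
#'   [generate_cohort()].
#' @param truth The matching `ground_truth`.
#' @return A numeric vector of per-sample case probabilities.
#' @export
oracle_scores <- function(cohort, truth) {
  stopifnot(inherits(cohort, "metab_cohort"), inherits(truth, "ground_truth"))
  if (ncol(cohort$intensities) != nrow(truth$batch_factors)) {
    abort("ground truth does not match cohort dimensions",
          class = "metabnet_dims_error")
  }
  n <- nrow(cohort$intensities)
  batch_idx <- match(cohort$samples$batch, colnames(truth$batch_factors))
  logx <- log(cohort$intensities) -
    t(log(truth$batch_factors[, batch_idx, drop = FALSE]))
  prior <- truth$class_prior
  lo <- rep(log(prior) - log1p(-prior), n)

  sg <- truth$signal
  for (j in seq_len(nrow(sg))) {
    x <- logx[, sg$index[j]]
    term <- dnorm(x, sg$mean_case[j], sqrt(sg$var_case[j]), log = TRUE) -
      dnorm(x, sg$mean_control[j], sqrt(sg$var_control[j]), log = TRUE)
    term[is.na(term)] <- 0
    lo <- lo + term
  }

  cp <- truth$coparents
  for (j in seq_len(nrow(cp))) {
    a <- logx[, cp$index_a[j]] - cp$mean_a[j]
    b <- logx[, cp$index_b[j]] - cp$mean_b[j]
    v <- cp$u_sd[j]^2 + cp$e_sd[j]^2
    cv <- -cp$u_sd[j]^2
    d <- cp$delta[j]
    both <- !is.na(a) & !is.na(b)
    # bivariate normal log-density difference (class shifts b's mean by delta)
    det2 <- v^2 - cv^2
    q <- function(aa, bb) (v * aa^2 - 2 * cv * aa * bb + v * bb^2) / det2
    term <- ifelse(both, -0.5 * (q(a, b - d) - q(a, b)), 0)
    only_b <- is.na(a) & !is.na(b)
    term[only_b] <- dnorm(b[only_b], d, sqrt(v), log = TRUE) -
      dnorm(b[only_b], 0, sqrt(v), log = TRUE)
    term[is.na(term)] <- 0
    lo <- lo + term
  }
  unname(stats::plogis(lo))
}

#' Closed-form Bayes-optimal AUC of the generating model
#'
#' Under the planted model both class-conditional distributions of the
#' informative coordinates are Gaussian with a common covariance, so the
#' optimal score is linear and the optimal AUC is `pnorm(D / sqrt(2))` where
#' `D` is the Mahalanobis distance between the class means. Signal
#' metabolites contribute `effect_size^2` each; each co-parent pair
#' contributes the quadratic form of its mean shift in the pair covariance.
#'
#' @param truth A `ground_truth`.
#' @return The Bayes-optimal AUC as a single number.
#' @export
oracle_auc <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  sg <- truth$signal
  d2 <- sum((sg$mean_case - sg$mean_control)^2 / sg$var_control)
  cp <- truth$coparents
  if (nrow(cp) > 0) {
    v <- cp$u_sd^2 + cp$e_sd^2
    cv <- -cp$u_sd^2
    d2 <- d2 + sum(cp$delta^2 * v / (v^2 - cv^2))
  }
  pnorm(sqrt(d2) / sqrt(2))
}
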