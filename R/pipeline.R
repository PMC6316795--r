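#' Configuration for a full study run
#'
#' Bundles every choice of the end-to-end workflow: the input (a
#' `metab_cohort` or a [synthetic_config()]), which classifiers to run,
#' the hyperparameter grids searched by cross-validation, fold and
#' permutation counts, and the master seed from which all stage seeds are
#' derived.
#'
#' @param synthetic A [synthetic_config()] describing data to simulate
#'   (ignored when `cohort` is given).
#' @param cohort An existing raw-scale `metab_cohort`.
#' @param classifier `"both"`, `"plsda"` or `"cgbn"`.
#' @param k_grid PLS component grid (default `1:70`, capped at feasibility).
#' @param bf_grid Log Bayes-factor threshold grid (default `2:30`).
#' @param folds Cross-validation folds (default 5).
#' @param realizations Permutation realizations (default 1000).
#' @param loading_threshold Influential-loading cutoff (default 2).
#' @param priors [cgbn_priors()] for the network.
#' @param max_parents Parent limit for the network (default 2).
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), cohort = NULL,
                            classifier = c("both", "plsda", "cgbn"),
                            k_grid = 1:70, bf_grid = 2:30, folds = 5,
                            realizations = 1000, loading_threshold = 2,
                            priors = cgbn_priors(), max_parents = 2,
                            seed = 1L) {
  classifier <- match.arg(classifier)
  structure(list(synthetic = synthetic, cohort = cohort,
                 classifier = classifier, k_grid = k_grid, bf_grid = bf_grid,
                 folds = folds, realizations = realizations,
                 loading_threshold = loading_threshold, priors = priors,
                 max_parents = max_parents, seed = as.integer(seed)),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "metabnet_stage_error", parent = e)
  })
}

#' Run the full study workflow
#'
#' Executes, in order: data simulation (or intake), batch merging, QC
#' filtering, half-minimum imputation, hyperparameter selection by
#' stratified cross-validation (PLS component count and/or Bayes-factor
#' threshold), bootstrap balancing and full-data refits, ROC convex-hull
#' evaluation with confidence intervals and operating points, DeLong
#' comparison of the two classifiers, label-permutation overfitting tests,
#' and the influential-loading / Markov-neighborhood variable lists with
#' their overlap. Every random step is driven by a seed derived from the
#' master seed, so identical configurations give identical reports.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list; see [report_metrics()] for the flat numeric
#'   summary and [write_report()] for serialisation.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  cohort <- with_stage("data", {
    if (!is.null(config$cohort)) config$cohort
    else {
      sim <- generate_cohort(config$synthetic)
      truth <- sim$truth
      sim$cohort
    }
  })
  prep <- with_stage("qc", prepare_matrix(cohort))
  core <- with_stage("model", {
    pipeline_core(prep$x, prep$labels, config)
  })
  stages <- tibble(
    stage = c("input", "qc", "analysis"),
    rows = c(nrow(cohort$intensities), nrow(prep$x), nrow(prep$x)),
    cols = c(ncol(cohort$intensities), ncol(prep$x), ncol(prep$x))
  )
  report <- c(list(
    config = config,
    config_hash = rlang::hash(config),
    seed = config$seed,
    stages = stages,
    qc = prep$reports,
    annotations = cohort$annotations,
    truth = truth
  ), core)
  class(report) <- "run_report"
  report
}

# QC front half: batch merge, filters, log transform, imputation.
prepare_matrix <- function(cohort) {
  merged <- if (length(unique(cohort$samples$batch)) > 1) {
    merge_batches(cohort)
  } else {
    list(cohort = cohort, report = NULL)
  }
  filt <- qc_filter(merged$cohort)
  done <- impute_missing(filt$cohort)
  list(x = done$intensities, labels = done$samples$label,
       samples = done$samples,
       reports = list(batch = merged$report, filter = filt$report))
}

# Shared back half of the workflow: selection, full-data refit, evaluation,
# comparison, permutation, variable lists.
pipeline_core <- function(x, labels, config, covariates = NULL) {
  seed <- config$seed
  run_plsda <- config$classifier %in% c("both", "plsda")
  run_cgbn <- config$classifier %in% c("both", "cgbn")
  out <- list()

  bal <- bootstrap_balance(labels, seed = seed + 11L)
  xb <- x[bal$index, , drop = FALSE]
  yb <- bal$label
  covb <- if (!is.null(covariates)) covariates[bal$index, , drop = FALSE]

  if (run_plsda) {
    kmax <- min(max(config$k_grid), ncol(x), nrow(x) - 1L)
    kg <- config$k_grid[config$k_grid <= kmax]
    sel <- select_n_components(x, labels, k_grid = kg, folds = config$folds,
                               seed = seed + 21L)
    fit <- fit_simpls(xb, yb, k = sel$k_best)
    scores <- predict_plsda(fit, xb)
    perm <- permutation_test(
      function(xx, yy) fit_simpls(xx, yy, k = min(sel$k_best, ncol(xx), nrow(xx) - 1L)),
      predict_plsda, x, labels,
      realizations = config$realizations, seed = seed + 31L
    )
    out$plsda <- list(
      k_best = sel$k_best, aucch_by_k = sel$aucch_by_k, model = fit,
      scores = scores, evaluation = roc_result(scores, yb),
      permutation = perm,
      loadings = influential_loadings(fit, component = 1,
                                      threshold = config$loading_threshold)
    )
  }
  if (run_cgbn) {
    selb <- select_bf_threshold(x, labels, thresholds = config$bf_grid,
                                folds = config$folds, seed = seed + 22L,
                                priors = config$priors,
                                max_parents = config$max_parents)
    net <- fit_cgbn(xb, yb, bf_threshold = selb$threshold_best,
                    priors = config$priors, max_parents = config$max_parents,
                    covariates = covb)
    scores <- predict_cgbn(net, xb, covariates = covb)
    perm <- permutation_test(
      function(xx, yy) fit_cgbn(xx, yy, bf_threshold = selb$threshold_best,
                                priors = config$priors,
                                max_parents = config$max_parents),
      function(m, xx) predict_cgbn(m, xx), x, labels,
      realizations = config$realizations, seed = seed + 32L
    )
    out$cgbn <- list(
      threshold_best = selb$threshold_best,
      aucch_by_threshold = selb$aucch_by_threshold, network = net,
      scores = scores, evaluation = roc_result(scores, yb),
      permutation = perm,
      neighborhood = markov_neighborhood(net)
    )
  }
  if (run_plsda && run_cgbn) {
    out$comparison <- delong_compare(out$cgbn$scores, out$plsda$scores, yb)
    out$overlap <- intersect(out$plsda$loadings$metabolite,
                             out$cgbn$neighborhood$node)
  }
  out$balanced <- tibble(n_total = nrow(xb), n_cases = sum(yb == 1),
                         n_controls = sum(yb == 0))
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  seed %d, config %s\n", x$seed, substr(x$config_hash, 1, 8)))
  cat(sprintf("  balanced dataset: %d (%d cases / %d controls)\n",
              x$balanced$n_total, x$balanced$n_cases, x$balanced$n_controls))
  if (!is.null(x$plsda)) {
    cat(sprintf("  PLS-DA: k = %d, full-data AUCCH %.3f (null %.3f +/- %.3f, p = %.3g)\n",
                x$plsda$k_best, x$plsda$evaluation$aucch,
                x$plsda$permutation$null_mean, x$plsda$permutation$null_sd,
                x$plsda$permutation$p_value))
  }
  if (!is.null(x$cgbn)) {
    cat(sprintf("  CGBN: log BF threshold = %d, full-data AUCCH %.3f (null %.3f +/- %.3f, p = %.3g)\n",
                x$cgbn$threshold_best, x$cgbn$evaluation$aucch,
                x$cgbn$permutation$null_mean, x$cgbn$permutation$null_sd,
                x$cgbn$permutation$p_value))
    cat(sprintf("  Markov neighborhood: %d variables\n",
                nrow(x$cgbn$neighborhood)))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  DeLong: AUC diff %.4f, p = %.3g; overlap %d metabolites\n",
                x$comparison$difference, x$comparison$p_value,
                length(x$overlap)))
  }
  invisible(x)
}

#' Sensitivity analyses around a covariate
#'
#' Re-runs the workflow in one of three modes: `add_covariate` enters the
#' covariate as a candidate explanatory variable alongside the metabolites
#' (an indicator column for PLS-DA; a discrete node placed immediately
#' after the phenotype for the network); `covariate_only` fits both models
#' on the covariate alone with no metabolites; `predict_covariate` swaps
#' the prediction target to the binarized covariate and re-runs on the
#' metabolites.
#'
#' @param config A [pipeline_config()].
#' @param mode One of `"add_covariate"`, `"covariate_only"`,
#'   `"predict_covariate"`.
#' @param covariate Covariate column name in the cohort samples table
#'   (default `"race"`).
#' @param positive_level For `predict_covariate`: the level coded 1
#'   (default the first sorted level).
#' @param binarize For `add_covariate`/`covariate_only`: collapse the
#'   covariate to `positive_level` vs the rest (default `FALSE`, all
#'   levels kept).
#' @return A `run_report` (comparison sections only where both classifiers
#'   ran).
#' @export
run_sensitivity <- function(config, mode = c("add_covariate", "covariate_only",
                                             "predict_covariate"),
                            covariate = "race", positive_level = NULL,
                            binarize = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$cohort)) config$cohort
            else generate_cohort(config$synthetic)$cohort
  if (!covariate %in% names(cohort$samples)) {
    abort(sprintf("covariate '%s' not present in the cohort", covariate))
  }
  cv_raw <- cohort$samples[[covariate]]
  if (is.numeric(cv_raw) && mode != "predict_covariate") {
    abort(paste0("continuous covariates cannot enter the network as discrete ",
                 "nodes; binarize or discretize '", covariate, "' first"),
          class = "metabnet_covariate_error")
  }
  if (is.null(positive_level)) positive_level <- sort(unique(as.character(cv_raw)))[1]
  cv <- if (binarize || mode == "predict_covariate") {
    factor(ifelse(as.character(cv_raw) == positive_level,
                  positive_level, paste0("non-", positive_level)))
  } else {
    factor(cv_raw)
  }
  prep <- with_stage("qc", prepare_matrix(cohort))
  cvp <- cv[match(prep$samples$sample_id, cohort$samples$sample_id)]
  ind <- stats::model.matrix(~ lv, data.frame(lv = cvp))[, -1, drop = FALSE]
  colnames(ind) <- paste0(covariate, "_", levels(cvp)[-1])

  core <- with_stage("model", switch(
    mode,
    add_covariate = {
      cfg <- config
      core_with_covariate(cbind(prep$x, ind), prep$labels, cfg,
                          covariates = data.frame(cvp) |> setNames(covariate),
                          x_cgbn = prep$x)
    },
    covariate_only = {
      cfg <- config
      cfg$k_grid <- cfg$k_grid[cfg$k_grid <= ncol(ind)]
      if (length(cfg$k_grid) == 0) cfg$k_grid <- 1L
      core_with_covariate(ind, prep$labels, cfg,
                          covariates = data.frame(cvp) |> setNames(covariate),
                          x_cgbn = prep$x[, 0, drop = FALSE])
    },
    predict_covariate = {
      labels2 <- as.integer(as.character(cvp) == positive_level)
      pipeline_core(prep$x, labels2, config)
    }
  ))
  report <- c(list(config = config, config_hash = rlang::hash(list(config, mode, covariate)),
                   seed = config$seed, mode = mode, covariate = covariate,
                   qc = prep$reports), core)
  class(report) <- "run_report"
  report
}

# Variant of pipeline_core where PLS-DA sees indicator columns while the
# network sees the covariate as a discrete node.
core_with_covariate <- function(x_plsda, labels, config, covariates, x_cgbn) {
  seed <- config$seed
  out <- list()
  bal <- bootstrap_balance(labels, seed = seed + 11L)
  yb <- bal$label
  run_plsda <- config$classifier %in% c("both", "plsda")
  run_cgbn <- config$classifier %in% c("both", "cgbn")
  if (run_plsda) {
    xb <- x_plsda[bal$index, , drop = FALSE]
    kmax <- min(max(config$k_grid), ncol(x_plsda), nrow(x_plsda) - 1L)
    kg <- config$k_grid[config$k_grid <= kmax]
    sel <- select_n_components(x_plsda, labels, k_grid = kg,
                               folds = config$folds, seed = seed + 21L)
    fit <- fit_simpls(xb, yb, k = sel$k_best)
    scores <- predict_plsda(fit, xb)
    out$plsda <- list(k_best = sel$k_best, aucch_by_k = sel$aucch_by_k,
                      model = fit, scores = scores,
                      evaluation = roc_result(scores, yb),
                      loadings = influential_loadings(fit, 1,
                                                      config$loading_threshold))
  }
  if (run_cgbn) {
    xb2 <- x_cgbn[bal$index, , drop = FALSE]
    covb <- covariates[bal$index, , drop = FALSE]
    net <- fit_cgbn(xb2, yb, bf_threshold = max(config$bf_grid[1], 2),
                    priors = config$priors, max_parents = config$max_parents,
                    covariates = covb)
    scores <- predict_cgbn(net, xb2, covariates = covb)
    out$cgbn <- list(threshold_best = net$bf_threshold, network = net,
                     scores = scores, evaluation = roc_result(scores, yb),
                     neighborhood = markov_neighborhood(net))
  }
  if (run_plsda && run_cgbn) {
    out$comparison <- delong_compare(out$cgbn$scores, out$plsda$scores, yb)
    out$overlap <- intersect(out$plsda$loadings$metabolite,
                             out$cgbn$neighborhood$node)
  }
  out$balanced <- tibble(n_total = length(yb), n_cases = sum(yb == 1),
                         n_controls = sum(yb == 0))
  out
}
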