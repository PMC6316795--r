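#' Tidy a fitted PLS-DA model
#'
#' One row per metabolite and component, with the weight, x-loading and
#' (standardized-scale) regression coefficient.
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @export
tidy.pls_model <- function(x, ...) {
  k <- x$n_components
  tibble(
    metabolite = rep(x$metabolites %||% paste0("V", seq_len(x$p)), k),
    component = rep(seq_len(k), each = x$p),
    weight = as.numeric(x$weights),
    loading = as.numeric(x$x_loadings),
    coefficient = rep(x$coefficients[, k], k)
  )
}

#' @export
glance.pls_model <- function(x, ...) {
  tibble(n_components = x$n_components, n = x$n, p = x$p,
         intercept = x$intercept)
}

#' Tidy a conditional Gaussian network
#'
#' The edge list with each edge's incremental log Bayes factor.
#'
#' @param x A `cgbn_network`.
#' @param ... Unused.
#' @export
tidy.cgbn_network <- function(x, ...) {
  as_tibble(x$edges)
}

#' @export
glance.cgbn_network <- function(x, ...) {
  mn <- if (!is.null(x$phenotype)) nrow(markov_neighborhood(x)) else NA_integer_
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         bf_threshold = x$bf_threshold, max_parents = x$max_parents,
         markov_neighborhood_size = mn)
}

#' @export
tidy.roc_result <- function(x, ...) {
  as_tibble(x$roc)
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, aucch = x$aucch,
         ci_lower = x$ci[1], ci_upper = x$ci[2],
         sensitivity = unname(x$operating_point["sensitivity"]),
         specificity = unname(x$operating_point["specificity"]),
         n_cases = x$n_cases, n_controls = x$n_controls)
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(realization = seq_along(x$null_aucch), aucch = x$null_aucch)
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean,
         null_sd = x$null_sd, p_value = x$p_value,
         realizations = x$realizations)
}

#' @export
glance.delong_comparison <- function(x, ...) {
  tibble(auc_a = x$auc_a, auc_b = x$auc_b, aucch_a = x$aucch_a,
         aucch_b = x$aucch_b, difference = x$difference,
         variance = x$variance, z = x$z, p_value = x$p_value)
}

#' Flat numeric summary of a pipeline run
#'
#' Collects the headline numbers of a [run_pipeline()] report into a single
#' named list suitable for JSON serialisation.
#'
#' @param report A `run_report`.
#' @return A named list of scalars.
#' @export
report_metrics <- function(report) {
  out <- list(seed = report$seed,
              balanced_n = report$balanced$n_total,
              balanced_cases = report$balanced$n_cases,
              balanced_controls = report$balanced$n_controls)
  if (!is.null(report$plsda)) {
    ev <- glance(report$plsda$evaluation)
    out$plsda_k <- report$plsda$k_best
    out$plsda_aucch <- ev$aucch
    out$plsda_ci_lower <- ev$ci_lower
    out$plsda_ci_upper <- ev$ci_upper
    out$plsda_sensitivity <- ev$sensitivity
    out$plsda_specificity <- ev$specificity
    out$plsda_n_influential <- nrow(report$plsda$loadings)
    if (!is.null(report$plsda$permutation)) {
      out$plsda_null_mean <- report$plsda$permutation$null_mean
      out$plsda_perm_p <- report$plsda$permutation$p_value
    }
  }
  if (!is.null(report$cgbn)) {
    ev <- glance(report$cgbn$evaluation)
    out$cgbn_bf_threshold <- report$cgbn$threshold_best
    out$cgbn_aucch <- ev$aucch
    out$cgbn_ci_lower <- ev$ci_lower
    out$cgbn_ci_upper <- ev$ci_upper
    out$cgbn_sensitivity <- ev$sensitivity
    out$cgbn_specificity <- ev$specificity
    out$cgbn_neighborhood_size <- nrow(report$cgbn$neighborhood)
    if (!is.null(report$cgbn$permutation)) {
      out$cgbn_null_mean <- report$cgbn$permutation$null_mean
      out$cgbn_perm_p <- report$cgbn$permutation$p_value
    }
  }
  if (!is.null(report$comparison)) {
    out$delong_difference <- report$comparison$difference
    out$delong_p <- report$comparison$p_value
    out$overlap_n <- length(report$overlap)
  }
  out
}
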