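#' Baseline characteristics table with case/control tests
#'
#' Compares each covariate between cases and controls: categorical
#' covariates by Pearson chi-square without continuity correction,
#' continuous covariates by Welch's two-sample t-test. Returns the usual
#' cohort-description table: counts and percentages per level (or mean and
#' SD) in each group, plus the test p-value. Empty category levels are
#' dropped with a warning.
#'
#' @param covariates Data frame of per-sample covariates (factors/character
#'   treated as categorical, numerics as continuous).
#' @param labels Binary vector (1 = case).
#' @return A tibble with one row per covariate level (or per continuous
#'   covariate): `variable`, `level`, `control_n`, `control_pct` (or
#'   mean/sd), `case_n`, `case_pct`, `statistic`, `df`, `p_value` (test
#'   values repeated on the variable's first row only).
#' @export
baseline_characteristics <- function(covariates, labels) {
  covariates <- as.data.frame(covariates)
  labels <- as.integer(labels)
  rows <- list()
  for (v in names(covariates)) {
    x <- covariates[[v]]
    if (is.numeric(x)) {
      tt <- t.test(x[labels == 1], x[labels == 0])
      rows[[v]] <- tibble(
        variable = v, level = "mean (SD)",
        control_n = mean(x[labels == 0]), control_pct = sd(x[labels == 0]),
        case_n = mean(x[labels == 1]), case_pct = sd(x[labels == 1]),
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value, test = "welch_t"
      )
    } else {
      f <- if (is.factor(x)) x else factor(x)
      if (any(table(f) == 0)) {
        warn(sprintf("dropping empty level(s) of '%s'", v))
        f <- droplevels(f)
      }
      tab <- table(f, factor(labels, levels = c(0, 1)))
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      lv <- levels(f)
      rows[[v]] <- tibble(
        variable = v, level = lv,
        control_n = as.numeric(tab[, "0"]),
        control_pct = as.numeric(tab[, "0"]) / sum(tab[, "0"]) * 100,
        case_n = as.numeric(tab[, "1"]),
        case_pct = as.numeric(tab[, "1"]) / sum(tab[, "1"]) * 100,
        statistic = c(unname(ct$statistic), rep(NA, length(lv) - 1)),
        df = c(unname(ct$parameter), rep(NA, length(lv) - 1)),
        p_value = c(ct$p.value, rep(NA, length(lv) - 1)),
        test = c("pearson_chisq", rep(NA, length(lv) - 1))
      )
    }
  }
  bind_rows(rows)
}

#' Pearson chi-square test from a printed contingency table
#'
#' Convenience for testing published count tables (levels x groups),
#' without continuity correction.
#'
#' @param counts Numeric matrix of counts (rows = levels, columns = groups).
#' @return A tibble (`statistic`, `df`, `p_value`).
#' @export
chisq_from_counts <- function(counts) {
  ct <- suppressWarnings(chisq.test(as.matrix(counts), correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Welch two-sample t-test from summary statistics
#'
#' Closed-form Welch test when only group means, SDs and sizes are
#' available (as in a published characteristics table).
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A tibble (`statistic` = t for mean2 - mean1, `df`
#'   (Welch-Satterthwaite), `p_value` two-sided).
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean2 - mean1) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  tibble(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}
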