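# DeLong structural components via midranks (handles ties, O(n log n)).
# v10[i] = P-hat(score_case_i > score_control) with ties counting half;
# v01[j] the mirror-image component for control j. mean(v10) = AUC.
delong_components <- function(scores, labels) {
  labels <- as.integer(labels)
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) abort("both classes must be present")
  tz <- rank(c(x, y), ties.method = "average")
  tx <- rank(x, ties.method = "average")
  ty <- rank(y, ties.method = "average")
  v10 <- (tz[seq_len(m)] - tx) / n
  v01 <- 1 - (tz[m + seq_len(n)] - ty) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong comparison of two paired classifiers
#'
#' Nonparametric comparison of the correlated AUCs of two score vectors
#' evaluated on the same samples, using DeLong structural-component
#' covariance estimates: `z = (AUC_A - AUC_B) / sqrt(var)` with a
#' two-sided normal p-value. The convex-hull areas (AUCCH) of both score
#' vectors are reported alongside the AUC test.
#'
#' @param scores_a,scores_b Paired score vectors on identical samples.
#' @param labels Binary labels (1 = case).
#' @return A `delong_comparison`: `auc_a`, `auc_b`, `aucch_a`, `aucch_b`,
#'   `difference` (AUC_A - AUC_B), `variance`, `z`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    abort("scores_a, scores_b and labels must be paired (equal length)")
  }
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- ca$auc - cb$auc
  if (diff == 0) {
    z <- 0; p <- 1
  } else if (v <= 0) {
    abort("zero variance with a nonzero AUC difference",
          class = "metabnet_delong_error")
  } else {
    z <- diff / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(
    auc_a = ca$auc, auc_b = cb$auc,
    aucch_a = aucch(roc_curve(scores_a, labels))$area,
    aucch_b = aucch(roc_curve(scores_b, labels))$area,
    difference = diff, variance = max(v, 0), z = z, p_value = p
  ), class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("<delong_comparison> AUC %.3f vs %.3f (AUCCH %.3f vs %.3f)\n",
              x$auc_a, x$auc_b, x$aucch_a, x$aucch_b))
  cat(sprintf("  difference %.4f, z = %.3f, two-sided p = %.4g\n",
              x$difference, x$z, x$p_value))
  invisible(x)
}

#' DeLong variance of a single empirical AUC
#'
#' @param scores,labels As in [roc_curve()].
#' @return Variance estimate of the empirical AUC.
#' @export
delong_variance <- function(scores, labels) {
  comp <- delong_components(scores, labels)
  var(comp$v10) / length(comp$v10) + var(comp$v01) / length(comp$v01)
}
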