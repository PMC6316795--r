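#' Empirical ROC curve
#'
#' Standard empirical ROC by descending score threshold, with tied scores
#' grouped into a single operating point. The curve always starts at
#' (0, 0) and ends at (1, 1).
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels Binary labels (1 = case).
#' @return A tibble (`threshold`, `fpr`, `tpr`); the first row is the
#'   all-negative point with threshold `Inf`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  if (any(!is.finite(scores))) abort("scores must be finite")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("both classes must be present", class = "metabnet_roc_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- !duplicated(s)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- c(which(grp[-1]) , length(s)) # last index of each tied block
  tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp[last] / n0),
    tpr = c(0, tp[last] / n1)
  )
}

#' Area under the ROC curve (trapezoid)
#'
#' @param roc A tibble from [roc_curve()].
#' @return The empirical AUC.
#' @export
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' ROC convex hull and its area (AUCCH)
#'
#' Upper convex hull of the ROC operating points together with the anchors
#' (0, 0) and (1, 1); every hull vertex is a realizable classifier (by
#' randomizing between the adjacent operating points), so the area under
#' the hull — by the trapezoid rule over its vertices — is the best
#' realizable performance of the score. AUCCH is always at least the
#' empirical AUC and at least 0.5 (the chance diagonal connects the
#' anchors).
#'
#' @param roc A tibble from [roc_curve()] (or any `fpr`/`tpr` point set).
#' @return A `roc_hull` list: `hull` (tibble of hull vertices in FPR
#'   order), `area` (the AUCCH), `auc` (trapezoid area of the input
#'   curve).
#' @export
aucch <- function(roc) {
  pts <- tibble(fpr = c(roc$fpr, 0, 1), tpr = c(roc$tpr, 0, 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  pts <- pts[!duplicated(pts[, c("fpr", "tpr")]), ]
  # Andrew's monotone chain, upper hull from (0,0) to (1,1)
  hx <- numeric(0); hy <- numeric(0)
  for (i in seq_len(nrow(pts))) {
    x <- pts$fpr[i]; y <- pts$tpr[i]
    while (length(hx) >= 2) {
      m <- length(hx)
      cross <- (hx[m] - hx[m - 1]) * (y - hy[m - 1]) -
        (hy[m] - hy[m - 1]) * (x - hx[m - 1])
      if (cross >= 0) { hx <- hx[-m]; hy <- hy[-m] } else break
    }
    hx <- c(hx, x); hy <- c(hy, y)
  }
  hull <- tibble(fpr = hx, tpr = hy)
  area <- sum(diff(hull$fpr) * (head(hull$tpr, -1) + hull$tpr[-1]) / 2)
  structure(list(hull = hull, area = area,
                 auc = if ("threshold" %in% names(roc)) auc_trapezoid(roc) else NA_real_),
            class = "roc_hull")
}

#' Full ROC evaluation of a score vector
#'
#' Bundles the empirical ROC, its convex hull and AUCCH, a DeLong-variance
#' Wald confidence interval applied to the AUCCH point estimate, and the
#' Youden-optimal operating point.
#'
#' @param scores,labels As in [roc_curve()].
#' @param level Confidence level (default 0.95).
#' @return A `roc_result` with elements `roc`, `hull`, `auc`, `aucch`,
#'   `ci` (length-2), `operating_point` (sensitivity, specificity).
#' @export
roc_result <- function(scores, labels, level = 0.95) {
  roc <- roc_curve(scores, labels)
  h <- aucch(roc)
  ci <- tryCatch(aucch_ci(scores, labels, level = level),
                 metabnet_ci_error = function(e) {
                   warn("degenerate scores: confidence interval undefined")
                   c(NA_real_, NA_real_)
                 })
  op <- operating_point(h)
  structure(list(roc = roc, hull = h$hull, auc = h$auc, aucch = h$area,
                 ci = ci, operating_point = op, level = level,
                 n_cases = sum(labels == 1), n_controls = sum(labels == 0)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f, AUCCH %.3f (%d%% CI %.3f-%.3f)\n",
              x$auc, x$aucch, round(100 * x$level), x$ci[1], x$ci[2]))
  cat(sprintf("  operating point: sensitivity %.3f, specificity %.3f\n",
              x$operating_point["sensitivity"],
              x$operating_point["specificity"]))
  invisible(x)
}

#' Wald confidence interval for the AUCCH
#'
#' Uses the DeLong structural-components variance of the empirical AUC as
#' the variance estimate, applied around the AUCCH point estimate, then
#' truncated to `[0, 1]`.
#'
#' @param scores,labels As in [roc_curve()].
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
aucch_ci <- function(scores, labels, level = 0.95) {
  comp <- delong_components(scores, labels)
  v <- var(comp$v10) / length(comp$v10) + var(comp$v01) / length(comp$v01)
  if (!is.finite(v) || (v == 0 && length(unique(scores)) == 1)) {
    abort("degenerate scores: AUC variance undefined",
          class = "metabnet_ci_error")
  }
  a <- aucch(roc_curve(scores, labels))$area
  z <- qnorm(1 - (1 - level) / 2)
  c(max(0, a - z * sqrt(v)), min(1, a + z * sqrt(v)))
}

#' Youden-optimal operating point on the convex hull
#'
#' The hull vertex maximising Youden's J (sensitivity + specificity - 1);
#' ties are broken toward higher specificity.
#'
#' @param x A `roc_hull` from [aucch()] (or an object containing one).
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
operating_point <- function(x) {
  hull <- if (inherits(x, "roc_hull")) x$hull else aucch(x)$hull
  sens <- hull$tpr
  spec <- 1 - hull$fpr
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  c(sensitivity = sens[best], specificity = spec[best])
}
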