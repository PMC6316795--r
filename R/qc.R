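#' Merge processing batches by control-median scaling
#'
#' For every metabolite, each non-reference batch is multiplied by the
#' factor `median(reference-batch controls) / median(that batch's controls)`
#' so the control medians of all batches agree. The reference batch is left
#' untouched. Metabolites whose factor is undefined (a zero or entirely
#' missing control median in some batch) are left unscaled and flagged.
#'
#' @param cohort A raw-scale `metab_cohort` with at least two batches and
#'   control samples (`label == 0`) in every batch.
#' @param reference_batch Batch identifier to scale the others to; default
#'   is the first batch in sort order.
#' @return A list with the rescaled `cohort` and a `report` tibble
#'   (metabolite, per-batch scale factors in a list column, `flagged`).
#' @export
merge_batches <- function(cohort, reference_batch = NULL) {
  stopifnot(inherits(cohort, "metab_cohort"))
  batches <- sort(unique(cohort$samples$batch))
  if (is.null(reference_batch)) reference_batch <- batches[1]
  if (!reference_batch %in% batches) {
    abort(sprintf("reference batch '%s' not present", reference_batch),
          class = "metabnet_batch_error")
  }
  if (length(batches) < 2) {
    warn("single batch: merge is an identity pass-through")
  }
  ctrl <- cohort$samples$label == 0
  for (b in batches) {
    if (!any(ctrl & cohort$samples$batch == b)) {
      abort(sprintf("batch '%s' has no control samples", b),
            class = "metabnet_batch_error")
    }
  }
  x <- cohort$intensities
  p <- ncol(x)
  med <- sapply(batches, function(b) {
    apply(x[ctrl & cohort$samples$batch == b, , drop = FALSE], 2,
          median, na.rm = TRUE)
  })
  med <- matrix(med, nrow = p, dimnames = list(colnames(x), batches))
  factors <- med[, reference_batch] / med
  factors[, reference_batch] <- 1
  flagged <- apply(factors, 1, function(f) any(!is.finite(f)))
  use <- factors
  use[!is.finite(use)] <- 1 # flagged metabolites left unscaled
  for (b in setdiff(batches, reference_batch)) {
    rows <- cohort$samples$batch == b
    x[rows, ] <- sweep(x[rows, , drop = FALSE], 2, use[, b], "*")
  }
  out <- cohort
  out$intensities <- x
  report <- tibble(
    metabolite = colnames(x),
    scale_factor = lapply(seq_len(p), function(j) setNames(factors[j, ], batches)),
    flagged = unname(flagged)
  )
  list(cohort = out, report = report)
}

#' Bias-corrected sample skewness
#'
#' Adjusted Fisher--Pearson standardized moment coefficient,
#' `g1 * sqrt(n (n - 1)) / (n - 2)`, the common default in statistical
#' software. Returns `NA` for fewer than 3 observations or zero variance.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / s2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Metabolite quality-control filter
#'
#' Applies, in order: (1) drop a metabolite if its missing fraction is 50%
#' or greater in any batch (inclusive boundary); (2) natural-log transform
#' the remaining observed intensities; (3) drop metabolites whose log values
#' have an interquartile range of zero; (4) drop metabolites whose log
#' values have bias-corrected sample skewness above 2 or below -2. The
#' report records the first rule that triggered for each dropped metabolite.
#' The returned cohort is on the log scale.
#'
#' @param cohort A raw-scale `metab_cohort` (typically after
#'   [merge_batches()]).
#' @param missing_threshold Missingness cutoff, default 0.5.
#' @param skew_threshold Absolute skewness cutoff, default 2.
#' @return A list with the filtered log-scale `cohort` and a `report`
#'   tibble: metabolite, status (`kept`, `dropped_missingness`,
#'   `dropped_iqr0`, `dropped_skew`), per-batch missing fractions (list
#'   column), skewness, plus counts before/after as attributes
#'   `n_before`/`n_after`.
#' @export
qc_filter <- function(cohort, missing_threshold = 0.5, skew_threshold = 2) {
  stopifnot(inherits(cohort, "metab_cohort"))
  x <- cohort$intensities
  batches <- sort(unique(cohort$samples$batch))
  missfrac <- sapply(batches, function(b) {
    colMeans(is.na(x[cohort$samples$batch == b, , drop = FALSE]))
  })
  missfrac <- matrix(missfrac, nrow = ncol(x),
                     dimnames = list(colnames(x), batches))
  status <- rep("kept", ncol(x))
  status[apply(missfrac >= missing_threshold, 1, any)] <- "dropped_missingness"

  # applying the filter to an already log-scale cohort is idempotent
  logx <- if (identical(cohort$scale, "log")) x else log(x)
  iqr <- apply(logx, 2, function(v) {
    q <- quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    q[2] - q[1]
  })
  skw <- apply(logx, 2, sample_skewness)
  status[status == "kept" & (is.na(iqr) | iqr == 0)] <- "dropped_iqr0"
  status[status == "kept" & !is.na(skw) & abs(skw) > skew_threshold] <- "dropped_skew"

  keep <- status == "kept"
  if (!any(keep)) {
    abort("all metabolites removed by QC: empty panel",
          class = "metabnet_empty_panel_error")
  }
  out <- cohort
  out$intensities <- logx[, keep, drop = FALSE]
  out$annotations <- cohort$annotations[keep, , drop = FALSE]
  out$scale <- "log"
  report <- tibble(
    metabolite = colnames(x), status = status,
    batch_missing_frac = lapply(seq_len(ncol(x)), function(j) {
      setNames(missfrac[j, ], batches)
    }),
    skewness = unname(skw)
  )
  attr(report, "n_before") <- ncol(x)
  attr(report, "n_after") <- sum(keep)
  list(cohort = out, report = report)
}

#' Half-minimum imputation of below-detection values
#'
#' Replaces each remaining missing log-value with the metabolite's minimum
#' observed log-value minus `log(2)` (half the minimum on the raw scale), the
#' usual stand-in for left-censored mass-spectrometry intensities.
#'
#' @param cohort A log-scale `metab_cohort` after [qc_filter()].
#' @return The completed `metab_cohort`.
#' @export
impute_missing <- function(cohort) {
  stopifnot(inherits(cohort, "metab_cohort"))
  if (!identical(cohort$scale, "log")) {
    abort("impute_missing expects a log-scale cohort (run qc_filter first)",
          class = "metabnet_scale_error")
  }
  x <- cohort$intensities
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (!any(nas)) next
    if (all(nas)) {
      abort(sprintf("metabolite '%s' is entirely missing (should have been filtered)",
                    colnames(x)[j]),
            class = "metabnet_impute_error")
    }
    x[nas, j] <- min(x[!nas, j]) - log(2)
  }
  out <- cohort
  out$intensities <- x
  out
}

#' Bootstrap class balancing
#'
#' Resamples the minority class with replacement up to the majority-class
#' count; every majority-class row is kept exactly once. With 59 cases and
#' 352 controls this yields 704 records (352 cases, 352 controls).
#'
#' @param labels Binary vector (1 = case).
#' @param seed Integer seed for the resampling draw.
#' @return A `balanced_dataset`: tibble with `index` (row in the original
#'   data) and `label`, plus the seed as an attribute.
#' @export
bootstrap_balance <- function(labels, seed = 1L) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("both classes must be present to balance",
          class = "metabnet_balance_error")
  }
  minority <- if (n1 <= n0) 1L else 0L
  n_major <- max(n1, n0)
  set.seed(seed)
  idx_major <- which(labels != minority)
  idx_minor <- sample(which(labels == minority), n_major, replace = TRUE)
  out <- tibble(index = c(idx_major, idx_minor),
                label = labels[c(idx_major, idx_minor)])
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("balanced_dataset", class(out))
  out
}

#' Column standardization with reusable transform
#'
#' Centers and scales each column to mean 0, SD 1 and keeps the centers and
#' scales so the identical transform can be applied to new samples.
#'
#' @param x Numeric matrix with no missing values.
#' @param centers,scales Optional precomputed transform (as returned in a
#'   previous call); when supplied they are applied as-is.
#' @return A list with `x` (transformed matrix), `centers`, `scales`.
#' @export
standardize <- function(x, centers = NULL, scales = NULL) {
  x <- as.matrix(x)
  if (is.null(centers)) {
    centers <- colMeans(x)
    scales <- apply(x, 2, sd)
    bad <- which(!is.finite(scales) | scales == 0)
    if (length(bad) > 0) {
      abort(sprintf("zero-variance column(s): %s",
                    paste(colnames(x)[bad], collapse = ", ")),
            class = "metabnet_scale_error")
    }
  }
  out <- sweep(sweep(x, 2, centers, "-"), 2, scales, "/")
  list(x = out, centers = centers, scales = scales)
}
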