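#' Fit a PLS-DA model with the SIMPLS algorithm
#'
#' Partial least squares against the binary class indicator (controls 0,
#' cases 1), computed with the SIMPLS sequence: weight vectors are extracted
#' to maximise covariance between the score `X w` and the centered response,
#' subject to orthogonality of successive score vectors, by deflating the
#' cross-covariance vector against an orthonormal basis of the x-loadings.
#' Columns of `x` are autoscaled (z-score) and the response mean-centered
#' before fitting; the transform is stored in the model so new samples are
#' treated identically.
#'
#' @param x Numeric predictor matrix (samples x metabolites), complete.
#' @param y Binary response vector (0 = control, 1 = case).
#' @param k Number of components, `1 <= k <= min(n - 1, p)`.
#' @param center,scale Whether to center / autoscale `x` (default both).
#' @return A `pls_model` with weights (`p x k`), x-loadings (`p x k`),
#'   y-loadings (`k`), scores (`n x k`), regression coefficients for every
#'   component count up to `k` (`p x k` matrix, column `j` = coefficients of
#'   the `j`-component model on the standardized scale), intercept
#'   (response mean), and the centering/scaling used. If `x` is
#'   rank-deficient the extraction stops early with a warning and `k` is
#'   reduced.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 8), 40)
#' y <- rbinom(40, 1, 0.5)
#' m <- fit_simpls(x, y, k = 2)
#' glance(m)
#' @export
fit_simpls <- function(x, y, k, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) abort("length(y) must equal nrow(x)")
  if (any(!is.finite(x))) abort("x must be complete and finite")
  kmax <- min(n - 1L, p)
  if (k < 1 || k > kmax) {
    abort(sprintf("k must be in 1..%d (min(n - 1, p))", kmax),
          class = "metabnet_k_error")
  }
  if (var(y) == 0) {
    abort("response is constant: zero covariance, no components to extract",
          class = "metabnet_degenerate_y_error")
  }
  centers <- if (center) colMeans(x) else rep(0, p)
  scales <- if (scale) apply(x, 2, sd) else rep(1, p)
  if (any(scales == 0)) {
    abort(sprintf("zero-variance column(s): %s",
                  paste(colnames(x)[scales == 0], collapse = ", ")),
          class = "metabnet_scale_error")
  }
  xs <- sweep(sweep(x, 2, centers, "-"), 2, scales, "/")
  y_mean <- mean(y)
  yc <- y - y_mean

  s <- drop(crossprod(xs, yc)) # cross-covariance vector
  W <- P <- matrix(0, p, k)
  Tm <- matrix(0, n, k)
  Q <- numeric(k)
  V <- matrix(0, p, k)
  a <- 0L
  for (comp in seq_len(k)) {
    if (sqrt(sum(s^2)) < 1e-12 * p) break
    r <- s
    t <- drop(xs %*% r)
    t <- t - mean(t)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-10) break
    t <- t / nt
    r <- r / nt
    pa <- drop(crossprod(xs, t))
    qa <- sum(yc * t)
    v <- pa
    if (comp > 1) {
      v <- v - V[, seq_len(comp - 1), drop = FALSE] %*%
        crossprod(V[, seq_len(comp - 1), drop = FALSE], pa)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v * drop(crossprod(v, s))
    a <- comp
    W[, a] <- r; P[, a] <- pa; Q[a] <- qa; Tm[, a] <- t; V[, a] <- v
  }
  if (a == 0L) {
    abort("no component could be extracted (zero cross-covariance)",
          class = "metabnet_degenerate_y_error")
  }
  if (a < k) {
    warn(sprintf("rank deficiency: stopped after %d of %d components", a, k))
    W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
    Tm <- Tm[, seq_len(a), drop = FALSE]; Q <- Q[seq_len(a)]
  }
  # coefficients of every nested j-component model (standardized scale)
  coefs <- sapply(seq_len(a), function(j) {
    drop(W[, seq_len(j), drop = FALSE] %*% Q[seq_len(j)])
  })
  coefs <- matrix(coefs, nrow = p)
  dimnames(W) <- dimnames(P) <- dimnames(coefs) <-
    list(colnames(x), paste0("comp", seq_len(a)))
  structure(list(
    n_components = a, weights = W, x_loadings = P, y_loadings = Q,
    scores = Tm, coefficients = coefs, intercept = y_mean,
    centers = centers, scales = scales, metabolites = colnames(x),
    n = n, p = p
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> SIMPLS, %d component(s), n = %d, p = %d\n",
              x$n_components, x$n, x$p))
  invisible(x)
}

#' Predict PLS-DA class scores
#'
#' Applies the stored standardization and the k-component regression
#' coefficients to new samples; the intercept anchors the training scores at
#' the 0/1 class coding, so scores behave like (unclipped) case
#' probabilities. Clipping to `[0, 1]` is for reporting only and must never
#' precede ROC construction.
#'
#' @param model A `pls_model`.
#' @param xnew Matrix of new samples; columns must cover the training
#'   metabolites (matched by name when available).
#' @param k Number of components to use (default: all fitted).
#' @param clip Clip scores to `[0, 1]` for reporting (default `FALSE`).
#' @return Numeric vector of continuous scores.
#' @export
predict_plsda <- function(model, xnew, k = model$n_components, clip = FALSE) {
  stopifnot(inherits(model, "pls_model"))
  xnew <- as.matrix(xnew)
  if (!is.null(model$metabolites) && !is.null(colnames(xnew))) {
    missing_cols <- setdiff(model$metabolites, colnames(xnew))
    if (length(missing_cols) > 0) {
      abort(paste0("new data lacks training metabolites: ",
                   paste(missing_cols, collapse = ", ")),
            class = "metabnet_columns_error")
    }
    xnew <- xnew[, model$metabolites, drop = FALSE]
  } else if (ncol(xnew) != model$p) {
    abort("column count mismatch with training panel",
          class = "metabnet_columns_error")
  }
  if (k < 1 || k > model$n_components) abort("k out of fitted range")
  xs <- sweep(sweep(xnew, 2, model$centers, "-"), 2, model$scales, "/")
  sc <- drop(xs %*% model$coefficients[, k]) + model$intercept
  if (clip) sc <- pmin(1, pmax(0, sc))
  sc
}

#' Influential loadings of a PLS component
#'
#' Selects the metabolites whose loading on a component is at or beyond a
#' symmetric threshold (default 2, closed at the boundary: a loading of
#' exactly 2 or -2 is selected), split by sign and sorted by absolute
#' loading. Can be applied to a fitted `pls_model` (using its x-loadings)
#' or directly to a data frame with a `loading` column (e.g. a published
#' loading table).
#'
#' @param x A `pls_model` or a data frame containing `metabolite` and
#'   `loading` columns.
#' @param component Component index (models only; default 1).
#' @param threshold Absolute loading threshold, default 2.
#' @param ... Unused.
#' @return A `loading_selection` tibble (metabolite, loading, sign) sorted
#'   by `abs(loading)` descending, with the component and threshold as
#'   attributes.
#' @export
influential_loadings <- function(x, ...) UseMethod("influential_loadings")

#' @rdname influential_loadings
#' @export
influential_loadings.pls_model <- function(x, component = 1, threshold = 2, ...) {
  if (component > x$n_components) abort("component exceeds fitted count")
  ld <- tibble(metabolite = x$metabolites %||% paste0("V", seq_len(x$p)),
               loading = unname(x$x_loadings[, component]))
  sel <- influential_loadings(ld, threshold = threshold)
  attr(sel, "component") <- component
  sel
}

#' @rdname influential_loadings
#' @export
influential_loadings.data.frame <- function(x, threshold = 2, ...) {
  stopifnot("loading" %in% names(x))
  sel <- x[x$loading >= threshold | x$loading <= -threshold, , drop = FALSE]
  sel <- as_tibble(sel)
  sel$sign <- ifelse(sel$loading >= 0, "positive", "negative")
  sel <- sel[order(-abs(sel$loading)), ]
  attr(sel, "threshold") <- threshold
  class(sel) <- c("loading_selection", class(sel))
  sel
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Choose the number of PLS components
#'
#' Evaluates a grid of component counts by either stratified 5-fold
#' cross-validation or a single stratified 2:1 holdout split on the original
#' (unbalanced) subjects; training folds are bootstrap-balanced, held-out
#' samples are scored untouched, and the held-out scores are pooled into one
#' ROC whose convex-hull area (AUCCH) is the selection criterion. Ties go to
#' the smallest `k`.
#'
#' @param x Complete predictor matrix on the original subjects.
#' @param y Original binary labels.
#' @param k_grid Candidate component counts (default `1:70`, capped at the
#'   feasible maximum).
#' @param strategy `"cv"` (default) or `"holdout"`.
#' @param folds Number of CV folds.
#' @param seed Integer seed for fold assignment and balancing.
#' @return A list with `k_best` and a tibble `aucch_by_k`.
#' @export
select_n_components <- function(x, y, k_grid = 1:70, strategy = c("cv", "holdout"),
                                folds = 5, seed = 1L) {
  strategy <- match.arg(strategy)
  x <- as.matrix(x)
  if (length(k_grid) == 0) abort("empty component grid")
  kmax <- max(k_grid)
  splits <- if (strategy == "cv") {
    make_cv_splits(y, folds, seed)
  } else {
    make_holdout_split(y, 2 / 3, seed)
  }
  pooled <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    bal <- bootstrap_balance(y[sp$train], seed = seed + i)
    xtr <- x[sp$train[bal$index], , drop = FALSE]
    ktr <- min(kmax, nrow(xtr) - 1L, ncol(xtr))
    fit <- fit_simpls(xtr, bal$label, k = ktr)
    pooled[[i]] <- lapply(k_grid[k_grid <= fit$n_components], function(kk) {
      tibble(k = kk, score = predict_plsda(fit, x[sp$test, , drop = FALSE], k = kk),
             label = y[sp$test])
    }) %>% bind_rows()
  }
  pooled <- bind_rows(pooled)
  aucch_by_k <- pooled %>%
    group_by(.data$k) %>%
    summarise(aucch = aucch(roc_curve(.data$score, .data$label))$area,
              .groups = "drop")
  best <- aucch_by_k %>%
    filter(.data$aucch == max(.data$aucch)) %>%
    arrange(.data$k)
  list(k_best = best$k[1], aucch_by_k = aucch_by_k)
}

# Stratified fold assignment on the original labels.
make_cv_splits <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  for (f in seq_len(folds)) {
    if (length(unique(y[fold == f])) < 2) {
      abort("a fold contains a single class; use fewer folds",
            class = "metabnet_fold_error")
    }
  }
  lapply(seq_len(folds), function(f) {
    list(train = which(fold != f), test = which(fold == f))
  })
}

make_holdout_split <- function(y, train_frac, seed) {
  set.seed(seed)
  train <- integer(0)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    train <- c(train, idx[seq_len(round(train_frac * length(idx)))])
  }
  train <- sort(train)
  list(list(train = train, test = setdiff(seq_along(y), train)))
}
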