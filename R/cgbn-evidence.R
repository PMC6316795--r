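#' Priors for conditional Gaussian Bayesian network learning
#'
#' Normal-inverse-gamma prior for every Gaussian family and a symmetric
#' Dirichlet prior for discrete families. Coefficients (including the
#' intercept) have a zero-mean Gaussian prior with precision `nu * I`
#' relative to the residual variance, and the residual variance has an
#' inverse-gamma prior with shape `alpha / 2` and scale
#' `alpha * sigma2 / 2`, so the marginal likelihood is a multivariate
#' Student-t. Metabolites are standardized before learning, which makes
#' `sigma2 = 1` the natural prior scale.
#'
#' @param nu Prior precision weight for regression coefficients (default 10).
#' @param alpha Prior degrees-of-freedom weight (default 10).
#' @param sigma2 Prior residual variance (default 1).
#' @param dirichlet_alpha Total Dirichlet concentration for discrete
#'   families (default `alpha`).
#' @return A `cgbn_priors` list.
#' @export
cgbn_priors <- function(nu = 10, alpha = 10, sigma2 = 1,
                        dirichlet_alpha = alpha) {
  vals <- c(nu = nu, alpha = alpha, sigma2 = sigma2,
            dirichlet_alpha = dirichlet_alpha)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all prior parameters must be strictly positive",
          class = "metabnet_prior_error")
  }
  structure(list(nu = nu, alpha = alpha, sigma2 = sigma2,
                 dirichlet_alpha = dirichlet_alpha),
            class = "cgbn_priors")
}

#' Log marginal likelihood of a Bayesian linear-Gaussian family
#'
#' Closed-form evidence of the normal-inverse-gamma model described in
#' [cgbn_priors()]: `y | beta, s2 ~ N(X beta, s2 I)`,
#' `beta | s2 ~ N(0, s2 (nu I)^-1)`, `s2 ~ IG(alpha/2, alpha sigma2/2)`.
#' An empty dataset has log marginal likelihood 0 (the empty product).
#'
#' @param child Numeric response values.
#' @param design Design matrix including the intercept column (same number
#'   of rows as `child`).
#' @param priors A [cgbn_priors()].
#' @return Log marginal likelihood (finite for all finite inputs).
#' @export
log_marginal_gaussian <- function(child, design, priors = cgbn_priors()) {
  design <- as.matrix(design)
  n <- length(child)
  if (n == 0) return(0)
  if (nrow(design) != n) abort("design rows must match child length")
  if (any(!is.finite(child)) || any(!is.finite(design))) {
    abort("non-finite values in child or design",
          class = "metabnet_nonfinite_error")
  }
  nig_logev(n = n, yy = sum(child^2), Xy = drop(crossprod(design, child)),
            XX = crossprod(design), priors = priors)
}

# Evidence from sufficient statistics (n, y'y, X'y, X'X).
nig_logev <- function(n, yy, Xy, XX, priors) {
  if (n == 0) return(0)
  d <- length(Xy)
  Ln <- XX + diag(priors$nu, d)
  a0 <- priors$alpha / 2
  b0 <- priors$alpha * priors$sigma2 / 2
  ch <- chol(Ln)
  mun <- backsolve(ch, forwardsolve(t(ch), Xy))
  an <- a0 + n / 2
  bn <- b0 + 0.5 * max(yy - sum(Xy * mun), 0)
  -n / 2 * log(2 * pi) + 0.5 * (d * log(priors$nu) - 2 * sum(log(diag(ch)))) +
    a0 * log(b0) - an * log(bn) + lgamma(an) - lgamma(a0)
}

# Dirichlet-multinomial evidence for a discrete child given discrete-parent
# configurations. `counts` is a matrix: rows = parent configs, cols = child
# levels. Total concentration A is spread evenly over the child's levels.
dirichlet_logev <- function(counts, priors) {
  counts <- as.matrix(counts)
  A <- priors$dirichlet_alpha
  K <- ncol(counts)
  nrow_tot <- rowSums(counts)
  sum(lgamma(A) - lgamma(A + nrow_tot)) +
    sum(lgamma(A / K + counts) - lgamma(A / K))
}

# ---- internal conditional-Gaussian data container -------------------------
#
# Partitions the rows by the joint configuration of all discrete variables
# and precomputes, per configuration, the Gram matrix of (1, continuous
# block). All family evidences used by the structure search are assembled
# from these Grams in O(1) per candidate.
cg_data <- function(cont, disc) {
  cont <- as.matrix(cont)
  storage.mode(cont) <- "double"
  n <- nrow(cont)
  if (is.null(disc) || length(disc) == 0) {
    disc <- data.frame(row.names = seq_len(n))
  }
  disc <- as.data.frame(lapply(as.data.frame(disc), function(v) {
    factor(v)
  }), optional = TRUE)
  if (ncol(disc) > 0) {
    key <- interaction(disc, drop = TRUE, lex.order = TRUE)
  } else {
    key <- factor(rep(1L, n))
  }
  groups <- split(seq_len(n), key)
  grams <- lapply(groups, function(rows) {
    z <- cbind(1, cont[rows, , drop = FALSE])
    list(n = length(rows), G = crossprod(z))
  })
  cfg <- if (ncol(disc) > 0) {
    unique_rows <- !duplicated(key)
    cf <- disc[unique_rows, , drop = FALSE]
    cf[order(key[unique_rows]), , drop = FALSE]
  } else {
    data.frame(row.names = 1)
  }
  list(cont = cont, disc = disc, n = n,
       cont_names = colnames(cont), disc_names = colnames(disc),
       grams = grams, configs = cfg, memo = new.env(parent = emptyenv()))
}

# Aggregate the atomic Grams over the configurations that agree on the
# chosen discrete parents. Returns a list of (n, G) groups. Aggregates are
# memoised (the search asks for the same few groupings thousands of times).
cg_groups <- function(cg, disc_parents) {
  key <- paste0(".", paste(sort(disc_parents), collapse = "\r"))
  hit <- cg$memo[[key]]
  if (!is.null(hit)) return(hit)
  out <- if (length(disc_parents) == 0) {
    list(list(n = cg$n, G = Reduce(`+`, lapply(cg$grams, `[[`, "G"))))
  } else {
    keys <- apply(cg$configs[, disc_parents, drop = FALSE], 1, paste,
                  collapse = "\r")
    unname(lapply(split(seq_along(cg$grams), keys), function(ix) {
      list(n = sum(vapply(cg$grams[ix], `[[`, 0, "n")),
           G = Reduce(`+`, lapply(cg$grams[ix], `[[`, "G")))
    }))
  }
  cg$memo[[key]] <- out
  out
}

# Evidence of a Gaussian family: continuous child `child` (index into the
# continuous block), continuous parents `cont_parents`, discrete parents
# `disc_parents` (names). Independent NIG evidence per discrete-parent
# configuration, summed.
gauss_family_logev <- function(cg, child, cont_parents, disc_parents, priors) {
  yi <- child + 1L
  di <- c(1L, cont_parents + 1L)
  sum(vapply(cg_groups(cg, disc_parents), function(g) {
    nig_logev(g$n, yy = g$G[yi, yi], Xy = g$G[di, yi, drop = TRUE],
              XX = g$G[di, di, drop = FALSE], priors = priors)
  }, 0))
}

# Vectorised evidence scan over candidate continuous parents for a Gaussian
# child, with zero or one continuous parent already in the design (the only
# cases that arise under max_parents = 2). Closed-form 2x2 / 3x3 solves on
# Gram entries, per discrete-parent configuration.
gauss_scan_logev <- function(cg, child, fixed_cont, disc_parents, candidates,
                             priors) {
  if (length(candidates) == 0) return(numeric(0))
  yi <- child + 1L
  ci <- candidates + 1L
  nu <- priors$nu
  a0 <- priors$alpha / 2
  b0 <- priors$alpha * priors$sigma2 / 2
  total <- numeric(length(candidates))
  for (g in cg_groups(cg, disc_parents)) {
    G <- g$G; n <- g$n
    an <- a0 + n / 2
    const <- -n / 2 * log(2 * pi) + a0 * log(b0) + lgamma(an) - lgamma(a0)
    if (length(fixed_cont) == 0) {
      a <- G[1, 1] + nu
      h <- diag(G)[ci] + nu
      gq <- G[1, ci]
      x1 <- G[1, yi]; x3 <- G[ci, yi]
      det <- a * h - gq^2
      Q <- (h * x1^2 - 2 * gq * x1 * x3 + a * x3^2) / det
      bn <- b0 + 0.5 * pmax(G[yi, yi] - Q, 0)
      total <- total + const + 0.5 * (2 * log(nu) - log(det)) - an * log(bn)
    } else {
      fi <- fixed_cont + 1L
      a <- G[1, 1] + nu; b <- G[1, fi]; d <- G[fi, fi] + nu
      gq <- G[1, ci]; e <- G[fi, ci]
      h <- diag(G)[ci] + nu
      x1 <- G[1, yi]; x2 <- G[fi, yi]; x3 <- G[ci, yi]
      det <- a * (d * h - e^2) - b * (b * h - e * gq) + gq * (b * e - d * gq)
      adj11 <- d * h - e^2; adj12 <- -(b * h - e * gq); adj13 <- b * e - d * gq
      adj22 <- a * h - gq^2; adj23 <- -(a * e - b * gq); adj33 <- a * d - b^2
      Q <- (x1^2 * adj11 + x2^2 * adj22 + x3^2 * adj33 +
              2 * x1 * x2 * adj12 + 2 * x1 * x3 * adj13 + 2 * x2 * x3 * adj23) / det
      bn <- b0 + 0.5 * pmax(G[yi, yi] - Q, 0)
      total <- total + const + 0.5 * (3 * log(nu) - log(det)) - an * log(bn)
    }
  }
  total
}

# Evidence of a discrete family: discrete child given discrete parents.
disc_family_logev <- function(cg, child, disc_parents, priors) {
  y <- cg$disc[[child]]
  if (length(disc_parents) == 0) {
    counts <- matrix(table(y), nrow = 1)
  } else {
    key <- interaction(cg$disc[disc_parents], drop = TRUE, lex.order = TRUE)
    counts <- as.matrix(table(key, y))
  }
  dirichlet_logev(counts, priors)
}

#' Log Bayes factor for adding one parent to a node's family
#'
#' The difference in log marginal likelihood between the child's family with
#' and without the candidate parent, all other parents held fixed. For a
#' continuous child the family is the conditional-Gaussian evidence (an
#' independent normal-inverse-gamma regression per configuration of its
#' discrete parents); for a discrete child it is Dirichlet-multinomial
#' evidence (discrete children admit only discrete parents).
#'
#' @param data Data frame holding the child, parents and candidate columns.
#' @param child Column name of the child node.
#' @param parents Character vector of current parent column names (may be
#'   empty).
#' @param candidate Column name of the candidate parent.
#' @param priors A [cgbn_priors()].
#' @param discrete Character vector naming the discrete columns of `data`
#'   (all others are treated as Gaussian).
#' @return The log Bayes factor in natural-log units.
#' @export
log_bayes_factor <- function(data, child, parents, candidate,
                             priors = cgbn_priors(), discrete = character()) {
  if (candidate %in% parents) {
    abort("candidate is already a parent", class = "metabnet_edge_error")
  }
  data <- as.data.frame(data)
  cols <- unique(c(child, parents, candidate, discrete))
  discrete <- intersect(discrete, cols)
  cont_cols <- setdiff(cols, discrete)
  cg <- cg_data(data[cont_cols], data[discrete])
  family_ev <- function(par) {
    dp <- intersect(par, discrete)
    if (child %in% discrete) {
      if (length(setdiff(par, discrete)) > 0) {
        abort("a discrete child cannot have continuous parents",
              class = "metabnet_cg_restriction_error")
      }
      disc_family_logev(cg, child, dp, priors)
    } else {
      cp <- match(setdiff(par, discrete), cg$cont_names)
      gauss_family_logev(cg, match(child, cg$cont_names), cp, dp, priors)
    }
  }
  family_ev(c(parents, candidate)) - family_ev(parents)
}
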