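#' Fit posterior-mean parameters of a conditional Gaussian network
#'
#' Given a fixed structure, computes posterior-mean parameters for every
#' family under the [cgbn_priors()] model. A Gaussian node gets, for each
#' configuration of its discrete parents, ridge-like posterior-mean
#' regression coefficients on its continuous parents (prior precision `nu`)
#' and the posterior-mean residual variance; a discrete node gets
#' Dirichlet-smoothed conditional frequencies. A discrete-parent
#' configuration observed in no sample falls back to the prior (zero
#' coefficients, prior-mean variance).
#'
#' @param net A `cgbn_network`.
#' @param data Data frame with a column per node (metabolites on the same
#'   standardized scale used for the search).
#' @param priors Priors; default those stored in the network.
#' @param nodes Nodes whose families to fit (default all; prediction only
#'   needs the phenotype and its children).
#' @return The network with a `params` element filled in.
#' @export
fit_parameters <- function(net, data, priors = net$priors,
                           nodes = net$nodes$name) {
  stopifnot(inherits(net, "cgbn_network"))
  data <- as.data.frame(data)
  nu <- priors$nu
  a0 <- priors$alpha / 2
  b0 <- priors$alpha * priors$sigma2 / 2
  A <- priors$dirichlet_alpha
  disc <- net$discrete
  for (d in disc) data[[d]] <- factor(data[[d]])
  params <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    node <- nodes[i]
    node_type <- net$nodes$type[match(node, net$nodes$name)]
    parents <- node_parents(net, node)
    dp <- intersect(parents, disc)
    cp <- setdiff(parents, disc)
    if (node_type == "discrete") {
      y <- data[[node]]
      K <- nlevels(y)
      if (length(dp) == 0) {
        counts <- matrix(table(y), nrow = 1, dimnames = list(NULL, levels(y)))
        cfgs <- data.frame(row.names = 1)
      } else {
        cfgs <- expand.grid(lapply(data[dp], levels),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        names(cfgs) <- dp
        counts <- matrix(0, nrow(cfgs), K, dimnames = list(NULL, levels(y)))
        key <- do.call(paste, c(data[dp], sep = "\r"))
        ckey <- do.call(paste, c(cfgs, sep = "\r"))
        tab <- table(factor(key, levels = ckey), y)
        counts[] <- as.matrix(tab)
      }
      cpt <- (counts + A / K) / (rowSums(counts) + A)
      params[[node]] <- list(type = "discrete", disc_parents = dp,
                             levels = levels(y), configs = cfgs, cpt = cpt)
    } else {
      if (length(dp) == 0) {
        cfgs <- data.frame(row.names = 1)
        masks <- list(rep(TRUE, nrow(data)))
      } else {
        cfgs <- expand.grid(lapply(data[dp], levels),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        names(cfgs) <- dp
        key <- do.call(paste, c(data[dp], sep = "\r"))
        ckey <- do.call(paste, c(cfgs, sep = "\r"))
        masks <- lapply(ckey, function(k) key == k)
      }
      coef_mat <- matrix(0, length(masks), 1 + length(cp))
      vars <- numeric(length(masks))
      for (m in seq_along(masks)) {
        rows <- masks[[m]]
        n <- sum(rows)
        if (n == 0) {
          coef_mat[m, ] <- 0
          vars[m] <- if (a0 > 1) b0 / (a0 - 1) else priors$sigma2
          next
        }
        X <- cbind(1, as.matrix(data[rows, cp, drop = FALSE]))
        y <- data[rows, node]
        Ln <- crossprod(X) + diag(nu, ncol(X))
        Xy <- drop(crossprod(X, y))
        mun <- solve(Ln, Xy)
        an <- a0 + n / 2
        bn <- b0 + 0.5 * max(sum(y^2) - sum(Xy * mun), 0)
        coef_mat[m, ] <- mun
        vars[m] <- bn / (an - 1)
      }
      params[[node]] <- list(type = "gaussian", disc_parents = dp,
                             cont_parents = cp, configs = cfgs,
                             coefficients = coef_mat, variance = vars)
    }
  }
  if (is.null(net$params)) net$params <- list()
  net$params[nodes] <- params
  net
}

#' Posterior probability of the phenotype from a fitted network
#'
#' Bayes rule over the phenotype's values: the posterior is proportional to
#' the phenotype's own (smoothed) prior times the product, over the
#' families in which the phenotype participates — its children in the
#' Markov neighborhood — of the conditional density of each child given its
#' parents with the phenotype clamped to that value. Nodes outside the
#' Markov neighborhood do not enter the computation.
#'
#' @param net A `cgbn_network` with fitted parameters.
#' @param newdata Data frame providing values for every Markov-neighborhood
#'   variable (metabolites on the training standardized scale).
#' @param positive Phenotype level whose probability is returned (default:
#'   the last level, i.e. "1" for 0/1 labels).
#' @return Numeric vector of posterior probabilities in (0, 1).
#' @export
predict_phenotype <- function(net, newdata, positive = NULL) {
  stopifnot(inherits(net, "cgbn_network"))
  if (is.null(net$params)) abort("network has no parameters; run fit_parameters()")
  ph <- net$phenotype
  if (is.null(ph)) abort("network has no phenotype node")
  newdata <- as.data.frame(newdata)
  n <- nrow(newdata)
  ph_par <- net$params[[ph]]
  lv <- ph_par$levels
  if (is.null(positive)) positive <- lv[length(lv)]
  children <- unique(net$edges$to[net$edges$from == ph])
  needed <- unique(c(ph_par$disc_parents, children,
                     unlist(lapply(children, function(c0) {
                       setdiff(node_parents(net, c0), ph)
                     }))))
  miss <- setdiff(needed, names(newdata))
  if (length(miss) == 0 && length(needed) > 0) {
    miss <- needed[vapply(newdata[needed], anyNA, TRUE)]
  }
  if (length(miss) > 0) {
    abort(paste0("missing Markov-neighborhood variable(s): ",
                 paste(miss, collapse = ", ")),
          class = "metabnet_columns_error")
  }
  loglik <- matrix(0, n, length(lv), dimnames = list(NULL, lv))
  for (vi in seq_along(lv)) {
    v <- lv[vi]
    ll <- log(cpt_lookup(ph_par, newdata, clamp = setNames(v, ph))[, v])
    for (child in children) {
      cp <- net$params[[child]]
      if (cp$type == "gaussian") {
        ll <- ll + gaussian_node_logdens(cp, newdata, clamp = setNames(v, ph),
                                         child_values = newdata[[child]])
      } else {
        pr <- cpt_lookup(cp, newdata, clamp = setNames(v, ph))
        obs <- as.character(newdata[[child]])
        ll <- ll + log(pr[cbind(seq_len(n), match(obs, cp$levels))])
      }
    }
    loglik[, vi] <- ll
  }
  m <- apply(loglik, 1, max)
  post <- exp(loglik - m)
  post <- post / rowSums(post)
  unname(post[, positive])
}

# Row-wise CPT lookup for a discrete node, with some discrete variables
# clamped to fixed values (e.g. the hypothesised phenotype level).
cpt_lookup <- function(par, newdata, clamp = character()) {
  n <- nrow(newdata)
  if (length(par$disc_parents) == 0) {
    return(matrix(par$cpt, n, length(par$levels), byrow = TRUE,
                  dimnames = list(NULL, par$levels)))
  }
  vals <- lapply(par$disc_parents, function(d) {
    if (d %in% names(clamp)) rep(clamp[[d]], n) else as.character(newdata[[d]])
  })
  key <- do.call(paste, c(vals, sep = "\r"))
  ckey <- do.call(paste, c(lapply(par$configs, as.character), sep = "\r"))
  idx <- match(key, ckey)
  if (anyNA(idx)) abort("unseen discrete-parent configuration in new data")
  out <- par$cpt[idx, , drop = FALSE]
  colnames(out) <- par$levels
  out
}

# Log conditional density of a Gaussian node's observed values given its
# parents, with clamped discrete values selecting the configuration.
gaussian_node_logdens <- function(par, newdata, clamp, child_values) {
  n <- nrow(newdata)
  if (length(par$disc_parents) == 0) {
    idx <- rep(1L, n)
  } else {
    vals <- lapply(par$disc_parents, function(d) {
      if (d %in% names(clamp)) rep(clamp[[d]], n) else as.character(newdata[[d]])
    })
    key <- do.call(paste, c(vals, sep = "\r"))
    ckey <- do.call(paste, c(lapply(par$configs, as.character), sep = "\r"))
    idx <- match(key, ckey)
    if (anyNA(idx)) abort("unseen discrete-parent configuration in new data")
  }
  X <- cbind(1, as.matrix(newdata[par$cont_parents]))
  mu <- rowSums(X * par$coefficients[idx, , drop = FALSE])
  dnorm(child_values, mu, sqrt(par$variance[idx]), log = TRUE)
}

#' Total log evidence of a network structure
#'
#' Sum of the per-node family marginal likelihoods. Evidence is
#' decomposable: adding an edge changes only the child's term.
#'
#' @param net A `cgbn_network`.
#' @param data Data frame of node columns.
#' @param priors Priors; default those stored in the network.
#' @return Total log marginal likelihood of the data under the structure.
#' @export
network_evidence <- function(net, data, priors = net$priors) {
  data <- as.data.frame(data)
  disc <- net$discrete
  cont_cols <- setdiff(net$nodes$name, disc)
  cg <- cg_data(data[cont_cols], data[disc])
  sum(vapply(net$nodes$name, function(node) {
    family_evidence(cg, net, node, node_parents(net, node), priors)
  }, 0))
}

family_evidence <- function(cg, net, node, parents, priors) {
  dp <- intersect(parents, cg$disc_names)
  if (node %in% cg$disc_names) {
    disc_family_logev(cg, node, dp, priors)
  } else {
    cp <- match(setdiff(parents, dp), cg$cont_names)
    gauss_family_logev(cg, match(node, cg$cont_names), cp, dp, priors)
  }
}

#' Fit a CGBN classifier end to end
#'
#' Convenience wrapper around the full learning sequence: z-score the
#' metabolite matrix, rank variables by Bayesian association with the
#' phenotype, run the K2 search at the given threshold, and fit
#' posterior-mean parameters. The standardization transform is stored so
#' new samples are scored on the training scale.
#'
#' @param x Complete numeric matrix (samples x metabolites).
#' @param labels Binary phenotype (1 = case).
#' @param bf_threshold Log Bayes-factor edge threshold (default 8).
#' @param priors A [cgbn_priors()].
#' @param max_parents Parent limit (default 2).
#' @param covariates Optional data frame of discrete per-sample covariates
#'   entered as candidate nodes immediately after the phenotype.
#' @return A fitted `cgbn_network` (with parameters, standardization and
#'   training data attached for re-thresholding).
#' @seealso [predict_cgbn()], [select_bf_threshold()]
#' @export
fit_cgbn <- function(x, labels, bf_threshold = 8, priors = cgbn_priors(),
                     max_parents = 2, covariates = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  std <- if (ncol(x) > 0) standardize(x)
         else list(x = x, centers = numeric(0), scales = numeric(0))
  df <- data.frame(phenotype = factor(labels, levels = sort(unique(labels))),
                   check.names = FALSE)
  disc <- "phenotype"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (cv in names(covariates)) df[[cv]] <- factor(covariates[[cv]])
    disc <- c(disc, names(covariates))
  }
  df <- cbind(df, as.data.frame(std$x))
  ordering <- rank_by_phenotype_association(df, "phenotype", priors, disc)
  net <- k2_search(df, ordering, bf_threshold, priors, max_parents,
                   phenotype = "phenotype", discrete = disc)
  net <- fit_parameters(net, df, priors)
  net$centers <- std$centers
  net$scales <- std$scales
  net$train_data <- df
  net$association <- ordering
  net
}

# Re-threshold a fitted network from its recorded greedy sequences and
# refit parameters on the stored training data.
refit_cgbn_threshold <- function(net, bf_threshold) {
  out <- truncate_network(net, bf_threshold)
  needed <- unique(c(net$phenotype,
                     out$edges$to[out$edges$from == net$phenotype]))
  out <- fit_parameters(out, net$train_data, net$priors, nodes = needed)
  out$centers <- net$centers
  out$scales <- net$scales
  out$train_data <- net$train_data
  out
}

#' Score new samples with a fitted CGBN classifier
#'
#' @param net A network from [fit_cgbn()].
#' @param xnew Matrix of raw-scale (same units as training) samples.
#' @param covariates Optional covariate data frame matching the training
#'   covariate nodes.
#' @return Posterior case probabilities.
#' @export
predict_cgbn <- function(net, xnew, covariates = NULL) {
  stopifnot(inherits(net, "cgbn_network"))
  xnew <- as.matrix(xnew)
  if (is.null(colnames(xnew))) colnames(xnew) <- names(net$centers)
  df <- if (length(net$centers) > 0) {
    as.data.frame(standardize(xnew[, names(net$centers), drop = FALSE],
                              centers = net$centers, scales = net$scales)$x)
  } else {
    data.frame(row.names = seq_len(nrow(xnew)))
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (cv in names(covariates)) df[[cv]] <- factor(covariates[[cv]])
  }
  predict_phenotype(net, df)
}
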