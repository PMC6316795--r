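#' Rank variables by Bayesian association with the phenotype
#'
#' Orders the candidate variables for the K2 search: the phenotype comes
#' first, then any discrete covariates, then the metabolites sorted by
#' decreasing log Bayes factor of the single-edge model
#' (phenotype -> metabolite) against the no-edge model. Ties are broken
#' deterministically by column name.
#'
#' @param data Data frame with one discrete phenotype column and numeric
#'   metabolite columns (plus optional discrete covariates).
#' @param phenotype Name of the phenotype column.
#' @param priors A [cgbn_priors()].
#' @param discrete Names of all discrete columns (default: the phenotype).
#' @return A tibble (`node`, `log_bf`, `rank`) whose row order is the K2
#'   ordering; `pull(node)` gives the plain ordering.
#' @export
rank_by_phenotype_association <- function(data, phenotype = "phenotype",
                                          priors = cgbn_priors(),
                                          discrete = phenotype) {
  data <- as.data.frame(data)
  stopifnot(phenotype %in% names(data))
  discrete <- union(discrete, phenotype)
  cont_cols <- setdiff(names(data), discrete)
  cg <- cg_data(data[cont_cols], data[discrete])
  # single-edge vs empty evidence, vectorised over all metabolites
  ev0 <- function(groups) {
    out <- numeric(length(cont_cols))
    for (g in groups) {
      G <- g$G; n <- g$n
      yi <- seq_along(cont_cols) + 1L
      a0 <- priors$alpha / 2
      b0 <- priors$alpha * priors$sigma2 / 2
      an <- a0 + n / 2
      Q <- G[1, yi]^2 / (G[1, 1] + priors$nu)
      bn <- b0 + 0.5 * pmax(diag(G)[yi] - Q, 0)
      out <- out + -n / 2 * log(2 * pi) +
        0.5 * (log(priors$nu) - log(G[1, 1] + priors$nu)) +
        a0 * log(b0) - an * log(bn) + lgamma(an) - lgamma(a0)
    }
    out
  }
  bf <- ev0(cg_groups(cg, phenotype)) - ev0(cg_groups(cg, character()))
  mets <- tibble(node = cont_cols, log_bf = bf) %>%
    arrange(desc(.data$log_bf), .data$node)
  out <- bind_rows(
    tibble(node = phenotype, log_bf = NA_real_),
    tibble(node = setdiff(discrete, phenotype), log_bf = NA_real_),
    mets
  )
  out$rank <- seq_len(nrow(out))
  out
}

# Greedy K2 parent selection. For each node in the ordering, repeatedly adds
# the predecessor whose inclusion gives the largest incremental log Bayes
# factor, as long as that log BF is at least `min_bf` and the node has fewer
# than `max_parents` parents. The greedy choice sequence does not depend on
# the threshold, so the recorded per-node sequences can be truncated at any
# threshold >= min_bf to give exactly the network K2 would have produced.
k2_core <- function(cg, ordering, priors, max_parents, min_bf) {
  disc_names <- cg$disc_names
  paths <- setNames(vector("list", length(ordering)), ordering)
  for (i in seq_along(ordering)) {
    child <- ordering[i]
    preds <- ordering[seq_len(i - 1L)]
    seq_parent <- character(0)
    seq_bf <- numeric(0)
    if (child %in% disc_names) {
      cand <- intersect(preds, disc_names) # CG restriction
      parents <- character(0)
      while (length(parents) < max_parents && length(cand) > 0) {
        base <- disc_family_logev(cg, child, parents, priors)
        bfs <- vapply(cand, function(cn) {
          disc_family_logev(cg, child, c(parents, cn), priors) - base
        }, 0)
        b <- which.max(bfs)
        if (bfs[b] < min_bf) break
        seq_parent <- c(seq_parent, cand[b])
        seq_bf <- c(seq_bf, bfs[b])
        parents <- c(parents, cand[b])
        cand <- cand[-b]
      }
    } else {
      j <- match(child, cg$cont_names)
      cand_d <- intersect(preds, disc_names)
      cand_c <- match(intersect(preds, cg$cont_names), cg$cont_names)
      par_d <- character(0)
      par_c <- integer(0)
      while (length(par_d) + length(par_c) < max_parents &&
             length(cand_d) + length(cand_c) > 0) {
        base <- gauss_family_logev(cg, j, par_c, par_d, priors)
        bf_d <- vapply(cand_d, function(dn) {
          gauss_family_logev(cg, j, par_c, c(par_d, dn), priors) - base
        }, 0)
        bf_c <- if (length(par_c) <= 1) {
          gauss_scan_logev(cg, j, par_c, par_d, cand_c, priors) - base
        } else {
          vapply(cand_c, function(cc) {
            gauss_family_logev(cg, j, c(par_c, cc), par_d, priors) - base
          }, 0)
        }
        bfs <- c(bf_d, bf_c)
        names_all <- c(cand_d, cg$cont_names[cand_c])
        # candidates listed in ordering order -> first max is the tie-break
        ord_pos <- match(names_all, ordering)
        keep <- order(ord_pos)
        bfs <- bfs[keep]; names_all <- names_all[keep]
        b <- which.max(bfs)
        if (length(b) == 0 || bfs[b] < min_bf) break
        chosen <- names_all[b]
        seq_parent <- c(seq_parent, chosen)
        seq_bf <- c(seq_bf, bfs[b])
        if (chosen %in% disc_names) {
          par_d <- c(par_d, chosen)
          cand_d <- setdiff(cand_d, chosen)
        } else {
          par_c <- c(par_c, match(chosen, cg$cont_names))
          cand_c <- setdiff(cand_c, match(chosen, cg$cont_names))
        }
      }
    }
    paths[[child]] <- list(parent = seq_parent, log_bf = seq_bf)
  }
  paths
}

new_cgbn_network <- function(ordering, types, paths, bf_threshold, priors,
                             max_parents, phenotype, discrete) {
  from <- to <- character(0)
  bf <- numeric(0)
  for (child in names(paths)) {
    sq <- paths[[child]]
    if (length(sq$parent) == 0) next
    ok <- cumall(sq$log_bf >= bf_threshold)
    if (!any(ok)) next
    from <- c(from, sq$parent[ok])
    to <- c(to, rep(child, sum(ok)))
    bf <- c(bf, sq$log_bf[ok])
  }
  edges <- tibble(from = from, to = to, log_bf = bf)
  net <- structure(list(
    nodes = tibble(name = ordering, type = types),
    edges = edges, paths = paths, ordering = ordering,
    bf_threshold = bf_threshold, priors = priors,
    max_parents = max_parents, phenotype = phenotype, discrete = discrete,
    params = NULL
  ), class = "cgbn_network")
  stopifnot(is_acyclic(net)) # edges run earlier -> later, but verify
  net
}

cumall <- function(x) cumprod(as.numeric(x)) > 0

is_acyclic <- function(net) {
  if (nrow(net$edges) == 0) return(TRUE)
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     vertices = net$nodes$name)
  igraph::is_dag(g)
}

#' K2 structure search over a fixed variable ordering
#'
#' Greedy parent selection for a conditional Gaussian Bayesian network: each
#' node in turn (following the ordering, phenotype first) greedily acquires
#' the predecessor parent with the largest incremental log Bayes factor, as
#' long as that log BF clears `bf_threshold` and the node has fewer than
#' `max_parents` parents. Edges only point from earlier to later nodes, so
#' the result is acyclic by construction (and verified). Discrete nodes may
#' only have discrete parents (the conditional-Gaussian restriction).
#'
#' @param data Data frame of node columns (metabolites standardized).
#' @param ordering Character vector of node names (phenotype first), or the
#'   tibble returned by [rank_by_phenotype_association()].
#' @param bf_threshold Log Bayes-factor cutoff for edge inclusion
#'   (natural-log units; the motivating study selected 8 by
#'   cross-validation).
#' @param priors A [cgbn_priors()].
#' @param max_parents Maximum number of parents per node (default 2).
#' @param phenotype Name of the phenotype node, or `NULL` for a network
#'   without one.
#' @param discrete Names of discrete columns.
#' @return A `cgbn_network`: nodes, an edge tibble (`from`, `to`, `log_bf`,
#'   each edge carrying its incremental log BF), the ordering, priors and
#'   threshold. Parameters are fitted separately by [fit_parameters()].
#' @export
k2_search <- function(data, ordering, bf_threshold = 8,
                      priors = cgbn_priors(), max_parents = 2,
                      phenotype = "phenotype",
                      discrete = if (is.null(phenotype)) character() else phenotype) {
  data <- as.data.frame(data)
  if (is.data.frame(ordering)) ordering <- ordering$node
  stopifnot(all(ordering %in% names(data)))
  discrete <- intersect(union(discrete, phenotype %||% character()), ordering)
  cont_cols <- setdiff(ordering, discrete)
  cg <- cg_data(data[cont_cols], data[discrete])
  types <- ifelse(ordering %in% discrete, "discrete", "gaussian")
  paths <- k2_core(cg, ordering, priors, max_parents, min_bf = bf_threshold)
  new_cgbn_network(ordering, types, paths, bf_threshold, priors,
                   max_parents, phenotype, discrete)
}

#' @export
print.cgbn_network <- function(x, ...) {
  cat(sprintf("<cgbn_network> %d nodes, %d edges (log BF threshold %.3g)\n",
              nrow(x$nodes), nrow(x$edges), x$bf_threshold))
  if (!is.null(x$phenotype)) {
    mn <- markov_neighborhood(x)
    cat(sprintf("  Markov neighborhood of '%s': %d node(s)\n",
                x$phenotype, nrow(mn)))
  }
  invisible(x)
}

# Re-derive the network at a (higher) threshold from the recorded greedy
# sequences; identical to rerunning k2_search at that threshold.
truncate_network <- function(net, bf_threshold) {
  new_cgbn_network(net$ordering, net$nodes$type, net$paths, bf_threshold,
                   net$priors, net$max_parents, net$phenotype, net$discrete)
}

#' Markov neighborhood of the phenotype node
#'
#' The phenotype's parents, children, and other parents of its children
#' (co-parents), tagged by role. Conditioning on these nodes renders the
#' phenotype independent of the rest of the network, so they are exactly
#' the variables needed for prediction. A node serving several roles is
#' tagged with the first of parent, child, co-parent that applies.
#'
#' @param net A `cgbn_network` with a phenotype node.
#' @return A tibble (`node`, `role`).
#' @export
markov_neighborhood <- function(net) {
  stopifnot(inherits(net, "cgbn_network"))
  if (is.null(net$phenotype)) abort("network has no phenotype node")
  ph <- net$phenotype
  parents <- net$edges$from[net$edges$to == ph]
  children <- net$edges$to[net$edges$from == ph]
  coparents <- setdiff(net$edges$from[net$edges$to %in% children], ph)
  out <- bind_rows(
    tibble(node = parents, role = "parent"),
    tibble(node = children, role = "child"),
    tibble(node = coparents, role = "co-parent")
  )
  out[!duplicated(out$node), ]
}

node_parents <- function(net, node) {
  net$edges$from[net$edges$to == node]
}

#' Select the Bayes-factor edge threshold by cross-validation
#'
#' Stratified k-fold cross-validation on the original (unbalanced) subjects:
#' each training set is bootstrap-balanced, a network is learned on it, and
#' held-out samples are scored untouched. The held-out scores are pooled per
#' threshold into one ROC and the threshold with the largest convex-hull
#' area (AUCCH) is returned, ties going to the larger (sparser) threshold.
#' Because the K2 greedy sequence is threshold-independent, each fold is
#' searched once at the smallest threshold and re-thresholded from the
#' recorded sequences.
#'
#' @param x Complete matrix of metabolite values on the original subjects.
#' @param labels Original binary labels.
#' @param thresholds Candidate log BF thresholds (default `2:30`).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed.
#' @param priors A [cgbn_priors()].
#' @param max_parents Parent limit (default 2).
#' @return A list with `threshold_best` and a tibble `aucch_by_threshold`.
#' @export
select_bf_threshold <- function(x, labels, thresholds = 2:30, folds = 5,
                                seed = 1L, priors = cgbn_priors(),
                                max_parents = 2) {
  if (length(thresholds) == 0) abort("empty threshold grid")
  x <- as.matrix(x)
  splits <- make_cv_splits(labels, folds, seed)
  pooled <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    bal <- bootstrap_balance(labels[sp$train], seed = seed + i)
    fit <- fit_cgbn(x[sp$train[bal$index], , drop = FALSE], bal$label,
                    bf_threshold = min(thresholds), priors = priors,
                    max_parents = max_parents)
    pooled[[i]] <- lapply(thresholds, function(t) {
      ft <- refit_cgbn_threshold(fit, t)
      tibble(threshold = t,
             score = predict_cgbn(ft, x[sp$test, , drop = FALSE]),
             label = labels[sp$test])
    }) %>% bind_rows()
  }
  pooled <- bind_rows(pooled)
  by_t <- pooled %>%
    group_by(.data$threshold) %>%
    summarise(aucch = aucch(roc_curve(.data$score, .data$label))$area,
              .groups = "drop")
  best <- by_t %>%
    filter(.data$aucch == max(.data$aucch)) %>%
    arrange(desc(.data$threshold))
  list(threshold_best = best$threshold[1], aucch_by_threshold = by_t)
}
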