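# Build a small labelled dataset with a known conditional-Gaussian structure.
gen_structured <- function(n, seed) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  a <- rnorm(n) + 1.2 * y
  b <- 0.8 * a + rnorm(n, 0, 0.7)
  c0 <- rnorm(n)
  data.frame(phenotype = y, a = a, b = b, c0 = c0)
}

test_that("phenotype-association ranking puts planted signals first", {
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 400
    y <- rep(0:1, each = n / 2)
    x <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, sprintf("m%02d", 1:20)))
    x[, 1:4] <- x[, 1:4] + 1.5 * y
    df <- data.frame(phenotype = factor(y), scale(x))
    rk <- rank_by_phenotype_association(df)
    mets <- rk$node[rk$node != "phenotype"]
    if (all(mets[1:4] %in% c("m01", "m02", "m03", "m04"))) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("ranking breaks ties between identical columns by name", {
  set.seed(61)
  v <- rnorm(100)
  df <- data.frame(phenotype = factor(rep(0:1, 50)), zz = v, aa = v)
  rk <- rank_by_phenotype_association(df)
  mets <- rk$node[rk$node != "phenotype"]
  expect_equal(mets, c("aa", "zz"))
  expect_equal(rk$node[1], "phenotype")
})

test_that("an infinite threshold yields an empty network", {
  d <- gen_structured(200, 62)
  df <- data.frame(phenotype = factor(d$phenotype), scale(d[, -1]))
  net <- k2_search(df, rank_by_phenotype_association(df), bf_threshold = Inf)
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(markov_neighborhood(net)), 0)
})

test_that("K2 recovers an order-respecting DAG from ample data", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 2000
    n1 <- rnorm(n); n2 <- rnorm(n)
    n3 <- 0.7 * n1 - 0.6 * n2 + rnorm(n, 0, 0.8)
    n4 <- 0.8 * n3 + rnorm(n, 0, 0.8)
    d <- data.frame(n1 = n1, n2 = n2, n3 = n3, n4 = n4)
    net <- k2_search(d, names(d), bf_threshold = 8, phenotype = NULL,
                     discrete = character())
    got <- sort(paste0(net$edges$from, "->", net$edges$to))
    if (identical(got, sort(c("n1->n3", "n2->n3", "n3->n4")))) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("K2's evidence never beats the exhaustive optimum and attains it
           under the true ordering", {
  set.seed(63)
  n <- 400
  n1 <- rnorm(n); n2 <- rnorm(n)
  n3 <- 0.7 * n1 - 0.6 * n2 + rnorm(n, 0, 0.8)
  n4 <- 0.8 * n3 + rnorm(n, 0, 0.8)
  d <- data.frame(n1 = n1, n2 = n2, n3 = n3, n4 = n4)
  nodes <- names(d)
  pr <- cgbn_priors()
  cgx <- metabnet:::cg_data(d, NULL)
  edges_all <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  edges_all <- edges_all[edges_all$from != edges_all$to, ]
  best <- -Inf
  for (mask in 0:(2^nrow(edges_all) - 1)) {
    sel <- edges_all[bitwAnd(bitwShiftR(mask, 0:(nrow(edges_all) - 1)), 1L) == 1L, ,
                     drop = FALSE]
    if (any(table(factor(sel$to, levels = nodes)) > 2)) next
    g <- igraph::graph_from_data_frame(sel, vertices = nodes)
    if (!igraph::is_dag(g)) next
    ev <- sum(vapply(nodes, function(nd) {
      metabnet:::gauss_family_logev(cgx, match(nd, nodes),
                                    match(sel$from[sel$to == nd], nodes),
                                    character(), pr)
    }, 0))
    best <- max(best, ev)
  }
  net <- k2_search(d, nodes, bf_threshold = 2, phenotype = NULL,
                   discrete = character())
  evk2 <- network_evidence(net, d)
  expect_lte(evk2, best + 1e-9)
  expect_equal(evk2, best, tolerance = 1e-9)
})

test_that("the Markov neighborhood is parents, children and co-parents", {
  # A -> D, D -> B, C -> B with D the phenotype
  paths <- list(A = list(parent = character(0), log_bf = numeric(0)),
                D = list(parent = "A", log_bf = 10),
                B = list(parent = c("D", "C"), log_bf = c(12, 9)),
                C = list(parent = character(0), log_bf = numeric(0)))
  net <- metabnet:::new_cgbn_network(
    ordering = c("A", "D", "B", "C")[c(1, 2, 4, 3)],
    types = c("gaussian", "discrete", "gaussian", "gaussian"),
    paths = paths[c(1, 2, 4, 3)], bf_threshold = 8,
    priors = cgbn_priors(), max_parents = 2, phenotype = "D", discrete = "D"
  )
  mn <- markov_neighborhood(net)
  expect_equal(mn$role[mn$node == "A"], "parent")
  expect_equal(mn$role[mn$node == "B"], "child")
  expect_equal(mn$role[mn$node == "C"], "co-parent")
  expect_equal(nrow(mn), 3)
})

test_that("every accepted edge clears the threshold and the graph is acyclic", {
  d <- gen_structured(600, 64)
  df <- data.frame(phenotype = factor(d$phenotype), scale(d[, -1]))
  net <- k2_search(df, rank_by_phenotype_association(df), bf_threshold = 8)
  expect_true(all(net$edges$log_bf >= 8))
  expect_true(metabnet:::is_acyclic(net))
  expect_true(all(table(net$edges$to) <= 2))
})

test_that("raising the threshold only removes edges (monotonicity)", {
  for (s in 1:3) {
    sw <- small_xy(seed = 70 + s)
    bal <- bootstrap_balance(sw$labels, seed = s)
    net <- fit_cgbn(sw$x[bal$index, ], bal$label, bf_threshold = 2)
    prev <- NULL
    for (t in seq(2, 30, by = 4)) {
      e <- metabnet:::truncate_network(net, t)$edges
      key <- paste(e$from, e$to)
      if (!is.null(prev)) expect_true(all(key %in% prev))
      prev <- key
    }
  }
})

test_that("network evidence decomposes over families", {
  sw <- small_xy(seed = 81)
  bal <- bootstrap_balance(sw$labels, seed = 4)
  net <- fit_cgbn(sw$x[bal$index, 1:20], bal$label, bf_threshold = 4)
  df <- net$train_data
  total <- network_evidence(net, df)
  cgx <- metabnet:::cg_data(df[setdiff(net$nodes$name, "phenotype")],
                            df["phenotype"])
  fam <- sum(vapply(net$nodes$name, function(nd) {
    metabnet:::family_evidence(cgx, net, nd,
                               metabnet:::node_parents(net, nd),
                               net$priors)
  }, 0))
  expect_equal(total, fam, tolerance = 1e-9)
  # adding an edge changes only the child's family term
  e1 <- net$edges[1, ]
  without <- net
  without$edges <- net$edges[-1, ]
  delta <- total - network_evidence(without, df)
  with_term <- metabnet:::family_evidence(
    cgx, net, e1$to, metabnet:::node_parents(net, e1$to), net$priors)
  without_term <- metabnet:::family_evidence(
    cgx, without, e1$to, metabnet:::node_parents(without, e1$to), net$priors)
  expect_equal(delta, with_term - without_term, tolerance = 1e-9)
})

test_that("threshold selection returns the lone grid value and reports the curve", {
  sw <- small_xy(seed = 82)
  sel <- select_bf_threshold(sw$x[, 1:15], sw$labels, thresholds = 7,
                             folds = 3, seed = 2)
  expect_equal(sel$threshold_best, 7)
  expect_named(sel$aucch_by_threshold, c("threshold", "aucch"))
})
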