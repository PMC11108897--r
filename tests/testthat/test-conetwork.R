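test_that("correlation matrix is symmetric with sane diagonal and p-values", {
  set.seed(1)
  m <- matrix(rlnorm(8 * 6), 8, 6, dimnames = list(NULL, sprintf("a%d", 1:6)))
  cm <- correlation_matrix(m)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 6))
  expect_true(all(cm$p >= 0 & cm$p <= 1))
  # rank invariance: a monotone transform correlates perfectly (spearman)
  m2 <- cbind(m, a7 = exp(m[, 1]))
  cm2 <- correlation_matrix(m2)
  expect_equal(cm2$r["a1", "a7"], 1)
  # constant columns are neutralised
  m3 <- cbind(m, flat = 5)
  cm3 <- correlation_matrix(m3)
  expect_true(all(cm3$r["flat", colnames(m)] == 0))
  expect_true(all(cm3$p["flat", colnames(m)] == 1))
  expect_error(correlation_matrix(m[1:3, ]), "4")
})

test_that("spearman coefficients match direct rank-formula arithmetic", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 0.5, 7, 1, 8, 2.2)
  m <- cbind(x = x, y = y, z = rnorm(6))
  cm <- correlation_matrix(m)
  # no ties: 1 - 6 sum(d^2) / (n(n^2-1))
  dr <- rank(x) - rank(y)
  expect_equal(cm$r["x", "y"], 1 - 6 * sum(dr^2) / (6 * 35))
})

test_that("network construction applies both cutoffs and keeps isolates", {
  r <- diag(5)
  ids <- sprintf("n%d", 1:5)
  dimnames(r) <- list(ids, ids)
  set_pair <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  r <- set_pair(r, 1, 2, 0.9)
  r <- set_pair(r, 1, 3, -0.8)
  r <- set_pair(r, 2, 3, 0.7)
  r <- set_pair(r, 4, 5, 0.9)
  p <- 1 - abs(r); diag(p) <- 0
  p[4, 5] <- p[5, 4] <- 0.5  # strong r but non-significant
  corr <- structure(list(r = r, p = p, node_ids = ids, method = "spearman"),
                    class = "corr_matrix")
  net <- build_network(corr, r_min = 0.65, p_max = 0.35)
  expect_identical(nrow(net$edges), 3L)
  expect_identical(nrow(net$nodes), 5L)   # isolates retained
  expect_setequal(net$edges$sign[net$edges$to == "n3"],
                  c("negative", "positive"))
  # monotonicity: tightening either cutoff never adds an edge
  e1 <- nrow(build_network(corr, r_min = 0.75, p_max = 0.35)$edges)
  e2 <- nrow(build_network(corr, r_min = 0.65, p_max = 0.1)$edges)
  expect_lte(e1, 3L)
  expect_lte(e2, 3L)
  expect_error(build_network(corr, r_min = 1.2), "0, 1")
})

test_that("module detection separates disjoint cliques and isolates", {
  adj <- matrix(0L, 7, 7)
  adj[1:3, 1:3] <- 1L; adj[4:6, 4:6] <- 1L
  diag(adj) <- 0L
  net <- detect_modules(network_from_adjacency(adj))
  mods <- net$nodes$module
  expect_identical(length(unique(mods)), 3L)  # two cliques + one singleton
  expect_identical(length(unique(mods[1:3])), 1L)
  expect_identical(length(unique(mods[4:6])), 1L)
  expect_false(mods[1] == mods[4])
  # edgeless graph: every node its own module
  lone <- detect_modules(network_from_adjacency(matrix(0L, 4, 4)))
  expect_identical(length(unique(lone$nodes$module)), 4L)
})

test_that("module recovery matches planted blocks on synthetic data", {
  ari <- vapply(1:10, function(s) {
    cfg <- scenario_config(seed = s, n_bridges = 0L)
    nd <- simulate_block_network_data(cfg)
    corr <- correlation_matrix(nd$abund)
    net <- build_network(corr, r_min = 0.5, p_max = 0.001,
                         node_meta = nd$node_meta)
    net <- detect_modules(net)
    found <- net$nodes$module
    truth <- nd$truth$block[net$nodes$node_id]
    # adjusted Rand index via pair counting
    tab <- table(found, truth)
    a <- sum(choose(tab, 2))
    b <- sum(choose(rowSums(tab), 2))
    cc <- sum(choose(colSums(tab), 2))
    n2 <- choose(sum(tab), 2)
    expected <- b * cc / n2
    (a - expected) / ((b + cc) / 2 - expected)
  }, numeric(1))
  expect_gte(mean(ari >= 0.9), 0.9)
})

test_that("Zi and Pi follow their defining formulas", {
  # star of one hub linked once into each of 4 cliques -> equal 4-way split
  adj <- matrix(0L, 13, 13)
  for (b in 0:3) {
    idx <- 2:4 + b * 3
    adj[idx, idx] <- 1L
    adj[1, idx[1]] <- adj[idx[1], 1] <- 1L
  }
  diag(adj) <- 0L
  net <- zi_pi(detect_modules(network_from_adjacency(adj)))
  hub <- net$nodes[1, ]
  expect_equal(hub$pi, 0.75)  # 1 - 4 (1/4)^2
  # all-internal nodes have Pi = 0
  internal <- net$nodes$degree == 2
  expect_true(all(net$nodes$pi[internal] == 0))
  # equal m-way splits for m = 2..6
  for (m in 2:6) {
    n_nodes <- 1 + 3 * m
    a2 <- matrix(0L, n_nodes, n_nodes)
    for (b in 0:(m - 1)) {
      idx <- 2:4 + b * 3
      a2[idx, idx] <- 1L
      a2[1, idx[1]] <- a2[idx[1], 1] <- 1L
    }
    diag(a2) <- 0L
    nn <- zi_pi(detect_modules(network_from_adjacency(a2)))
    expect_equal(nn$nodes$pi[1], 1 - 1 / m)
  }
})

test_that("role classification is total and matches the threshold table", {
  expect_identical(classify_role(0.3, 0.5), "module hub")
  expect_identical(classify_role(0.1, 0.7), "connector")
  expect_identical(classify_role(0.3, 0.7), "network hub")
  expect_identical(classify_role(0.1, 0.5), "peripheral")
  # boundary cases: thresholds are strict
  expect_identical(classify_role(0.25, 0.62), "peripheral")
  set.seed(2)
  roles <- classify_role(rnorm(500), runif(500))
  expect_true(all(roles %in% c("peripheral", "module hub", "connector",
                               "network hub")))
})

test_that("centralities match hand values on canonical graphs", {
  # path a-b-c
  path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  net <- network_from_adjacency(path3)
  bc <- betweenness_centrality(net)
  cc <- closeness_centrality(net)
  expect_equal(unname(bc), c(0, 1, 0))
  expect_equal(unname(cc), c(2 / 3, 1, 2 / 3))
  # star with 5 leaves: centre carries all C(5,2) pairs
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1
  expect_equal(unname(betweenness_centrality(network_from_adjacency(star))),
               c(10, rep(0, 5)))
  # complete graph: closeness 1 everywhere
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(unname(closeness_centrality(network_from_adjacency(k4))),
               rep(1, 4))
  # isolated node has closeness 0 by convention
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(unname(closeness_centrality(network_from_adjacency(iso)))[3], 0)
})

test_that("centralities agree exactly with brute-force path enumeration", {
  for (s in 1:40) {
    n <- sample(4:10, 1)
    adj <- random_adjacency(n, p = 0.35, seed = s)
    net <- network_from_adjacency(adj)
    expect_equal(unname(betweenness_centrality(net)), brute_betweenness(adj),
                 tolerance = 1e-12)
    expect_equal(unname(closeness_centrality(net)), brute_closeness(adj),
                 tolerance = 1e-12)
  }
})

test_that("betweenness mass on trees equals interior-pair counts", {
  # on a tree every pair has exactly one path: sum of BC equals the
  # number of (pair, interior-vertex) incidences
  set.seed(3)
  for (rep in 1:5) {
    n <- 8
    # random tree via random parent links
    adj <- matrix(0L, n, n)
    for (v in 2:n) {
      u <- sample(seq_len(v - 1), 1)
      adj[u, v] <- adj[v, u] <- 1L
    }
    dimnames(adj) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    net <- network_from_adjacency(adj)
    d <- bfs_distances(adj)
    interior <- sum(d[upper.tri(d)] - 1)  # path of length L has L-1 interiors
    expect_equal(sum(betweenness_centrality(net)), interior)
  }
})

test_that("network summaries follow their conventions", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  s <- network_summary(network_from_adjacency(tri))
  expect_equal(s$average_degree, 2)
  expect_equal(s$average_path_length, 1)
  path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  s2 <- network_summary(network_from_adjacency(path3))
  expect_equal(s2$average_degree, 4 / 3)
  expect_equal(s2$average_path_length, 4 / 3)
  # two disjoint edges: only connected pairs counted
  two <- matrix(0, 4, 4); two[1, 2] <- two[2, 1] <- two[3, 4] <- two[4, 3] <- 1
  s3 <- network_summary(network_from_adjacency(two))
  expect_equal(s3$average_degree, 1)
  expect_equal(s3$average_path_length, 1)
  # edgeless graph has no defined path length
  s4 <- network_summary(network_from_adjacency(matrix(0, 3, 3)))
  expect_true(is.na(s4$average_path_length))
})

test_that("cross-kingdom comparison reports tests, medians, exceedances", {
  adj <- random_adjacency(12, p = 0.4, seed = 9)
  kingdom <- rep(c("bacteria", "fungi"), each = 6)
  net <- network_centralities(network_from_adjacency(adj, kingdom = kingdom))
  cmp <- cross_kingdom_compare(net, bc_threshold = 1e6)
  expect_named(cmp$exceed_bc, c("fungi", "bacteria"))
  expect_equal(unname(cmp$exceed_bc), c(0, 0))  # threshold above every BC
  expect_true(cmp$bc_test$p_value > 0 && cmp$bc_test$p_value <= 1)
  solo <- network_from_adjacency(adj, kingdom = rep("bacteria", 12))
  expect_error(cross_kingdom_compare(solo), "both kingdoms")
})

test_that("planted fungal bridges dominate betweenness across seeds", {
  res <- vapply(1:10, function(s) {
    cfg <- scenario_config(seed = s)
    nd <- simulate_block_network_data(cfg)
    corr <- correlation_matrix(nd$abund)
    net <- build_network(corr, r_min = 0.5, p_max = 0.001,
                         node_meta = nd$node_meta)
    net <- network_centralities(net)
    cmp <- cross_kingdom_compare(net, bc_threshold = 100)
    bridges_top <- all(rank(-net$nodes$bc)[net$nodes$node_id %in%
                                             nd$truth$bridge_ids] <=
                         0.1 * nrow(net$nodes))
    c(top = bridges_top,
      signif = cmp$median_bc["fungi"] > cmp$median_bc["bacteria"] &&
        cmp$bc_test$p_value < 0.05)
  }, logical(2))
  expect_gte(mean(res["top", ]), 0.8)
  expect_gte(mean(res["signif", ]), 0.8)
})

test_that("network export writes graphml and tsv round-trippable tables", {
  adj <- random_adjacency(6, p = 0.5, seed = 4)
  net <- network_centralities(detect_modules(network_from_adjacency(adj)))
  g <- tempfile(fileext = ".graphml")
  e <- tempfile(fileext = ".tsv")
  nn <- tempfile(fileext = ".tsv")
  write_network(net, g, e, nn)
  expect_true(file.exists(g) && file.exists(e) && file.exists(nn))
  edges <- read.table(e, header = TRUE, sep = "\t")
  expect_identical(nrow(edges), nrow(net$edges))
  nodes <- read.table(nn, header = TRUE, sep = "\t")
  expect_identical(nrow(nodes), nrow(net$nodes))
})
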