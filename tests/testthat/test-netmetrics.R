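two_cliques <- function(size = 5) {
  n <- 2 * size
  A <- matrix(0L, n, n)
  A[1:size, 1:size] <- 1L
  A[(size + 1):n, (size + 1):n] <- 1L
  diag(A) <- 0L
  dimnames(A) <- list(sprintf("R%03d", 1:n), sprintf("R%03d", 1:n))
  hubgenes:::binary_graph_from_adjacency(A)
}

test_that("Louvain recovers two disconnected cliques with Q = 0.5", {
  g <- two_cliques(5)
  p <- louvain_partition(g, gamma = 1, seed = 1)
  expect_equal(p$n_modules, 2)
  expect_equal(p$labels, rep(1:2, each = 5))
  expect_equal(p$modularity, 0.5, tolerance = 1e-12)
})

test_that("modularity matches the brute-force double-sum definition", {
  for (seed in 1:5) {
    g <- random_graph(30, density = 0.2, seed = seed)
    for (gamma in c(1, 2)) {
      p <- louvain_partition(g, gamma = gamma, seed = seed)
      expect_equal(p$modularity,
                   oracle_modularity(g$adjacency, p$labels, gamma),
                   tolerance = 1e-10)
      # at gamma = 1, Louvain beats the trivial one-module partition (Q = 0)
      if (gamma == 1) {
        expect_equal(oracle_modularity(g$adjacency, rep(1, 30), 1), 0,
                     tolerance = 1e-12)
        expect_gte(p$modularity, -1e-12)
      }
    }
  }
  expect_equal(oracle_modularity(two_cliques(4)$adjacency, rep(1, 8), 1), 0)
})

test_that("consensus partition recovers planted modules and reduces to one run", {
  pp <- planted_partition_graph(n_modules = 8, n_per_module = 25,
                                p_in = 0.8, p_out = 0.02, seed = 1)
  cp <- consensus_partition(pp$graph, gamma = 1, n_runs = 20, seed = 1)
  expect_gt(ari(cp$labels, pp$labels), 0.9)
  expect_true(isSymmetric(cp$co_classification))
  expect_equal(unique(diag(cp$co_classification)), 1)

  # n_runs = 1 is a single Louvain run with the derived seed
  one <- consensus_partition(pp$graph, gamma = 1, n_runs = 1, seed = 5)
  single <- louvain_partition(pp$graph, gamma = 1,
                              seed = hubgenes:::derive_seed(5, 1))
  expect_equal(one$labels, single$labels)

  # higher resolution yields at least as many modules
  cp2 <- consensus_partition(pp$graph, gamma = 2, n_runs = 20, seed = 1)
  expect_gte(cp2$n_modules, cp$n_modules)
})

test_that("consensus labels are invariant under region relabelling", {
  pp <- planted_partition_graph(n_modules = 4, n_per_module = 15,
                                p_in = 0.8, p_out = 0.02, seed = 3)
  cp <- consensus_partition(pp$graph, gamma = 1, n_runs = 10, seed = 2)
  set.seed(42)
  perm <- sample(60)
  A2 <- pp$graph$adjacency[perm, perm]
  g2 <- hubgenes:::binary_graph_from_adjacency(A2)
  cp2 <- consensus_partition(g2, gamma = 1, n_runs = 10, seed = 2)
  expect_equal(ari(cp2$labels, cp$labels[perm]), 1)
})

test_that("nodal metrics match the per-edge loop oracle", {
  for (seed in 1:5) {
    g <- random_graph(40, density = 0.12, seed = seed)
    set.seed(seed)
    labels <- sample(1:4, 40, replace = TRUE)
    part <- structure(list(labels = labels, gamma = 1,
                           n_modules = max(labels)),
                      class = "modular_partition")
    got <- nodal_metrics(g, part)
    want <- oracle_nodal(g$adjacency, labels, g$coords)
    for (col in c("k", "k_intra", "k_inter", "pc", "d"))
      expect_equal(got[[col]], want[[col]], tolerance = 1e-10)
    # degree identities
    expect_equal(sum(got$k), 2 * nrow(g$edges))
    intra_edges <- sum(labels[g$edges$i] == labels[g$edges$j])
    expect_equal(sum(got$k_intra), 2 * intra_edges)
    # PC bounds: zero iff the node's edges concentrate in a single module
    ok <- got$k > 0
    expect_true(all(got$pc[ok] >= 0 & got$pc[ok] < 1))
    expect_true(all(got$pc[ok & got$k_inter == 0] == 0))
    one_module <- vapply(seq_len(40), function(i) {
      nbr <- which(g$adjacency[i, ] == 1)
      length(unique(labels[nbr])) == 1
    }, logical(1))
    expect_equal(got$pc[ok] == 0, one_module[ok])
  }
})

test_that("participation coefficient closed forms hold", {
  # all 6 edges inside own module -> PC = 0
  g <- two_cliques(7)
  part <- structure(list(labels = rep(1:2, each = 7), gamma = 1,
                         n_modules = 2), class = "modular_partition")
  m <- nodal_metrics(g, part)
  expect_true(all(m$pc == 0))
  expect_true(all(m$k == 6))

  # star node with one edge to each of 4 modules -> PC = 0.75
  A <- matrix(0L, 5, 5); A[1, 2:5] <- 1L; A[2:5, 1] <- 1L
  dimnames(A) <- list(sprintf("R%03d", 1:5), sprintf("R%03d", 1:5))
  gs <- hubgenes:::binary_graph_from_adjacency(A)
  ps <- structure(list(labels = c(1, 1, 2, 3, 4), gamma = 1, n_modules = 4),
                  class = "modular_partition")
  ms <- nodal_metrics(gs, ps)
  expect_equal(ms$pc[1], 0.75)
})

test_that("complete graph has C = 1, L = 1; rewiring preserves degrees", {
  A <- matrix(1L, 10, 10); diag(A) <- 0L
  dimnames(A) <- list(sprintf("R%03d", 1:10), sprintf("R%03d", 1:10))
  g <- hubgenes:::binary_graph_from_adjacency(A)
  gm <- global_metrics(g, n_null = 3, seed = 1)
  expect_equal(gm$C, 1)
  expect_equal(gm$L, 1)

  gr <- random_graph(30, density = 0.15, seed = 4)
  ig <- hubgenes:::as_igraph(gr)
  rw <- hubgenes:::rewire_connected(ig, swaps_per_edge = 10)
  expect_equal(sort(igraph::degree(rw)), sort(igraph::degree(ig)))
})

test_that("normalized rich club is near 1 for Erdos-Renyi graphs", {
  devs <- unlist(lapply(1:20, function(seed) {
    set.seed(seed)
    ig <- igraph::sample_gnp(60, 0.25)
    while (!igraph::is_connected(ig)) ig <- igraph::sample_gnp(60, 0.25)
    A <- igraph::as_adjacency_matrix(ig, sparse = FALSE)
    dimnames(A) <- list(sprintf("R%03d", 1:60), sprintf("R%03d", 1:60))
    g <- hubgenes:::binary_graph_from_adjacency(A)
    gm <- global_metrics(g, n_null = 20, seed = seed)
    rc <- gm$rich_club
    nk <- vapply(rc$k, function(k) sum(rowSums(A) > k), numeric(1))
    rc$phi_norm[nk >= 10] - 1
  }))
  expect_lt(abs(mean(devs)), 0.1)
})

test_that("class ANOVA matches the explicit sum-of-squares oracle", {
  # identical value multisets in two classes -> F = 0
  v <- c(1, 2, 3, 1, 2, 3)
  cl <- rep(c("a", "b"), each = 3)
  expect_equal(class_anova(v, cl)$F, 0)

  # 285 regions, 7 classes -> df = (6, 278)
  set.seed(11)
  v2 <- rnorm(285)
  cl2 <- sample(1:7, 285, replace = TRUE)
  res <- class_anova(v2, cl2)
  expect_equal(res$df1, 6)
  expect_equal(res$df2, 278)

  # random data: match the textbook between/within SS computation
  grand <- mean(v2)
  ssb <- sum(tapply(v2, cl2, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(v2, cl2, function(x) sum((x - mean(x))^2)))
  F_direct <- (ssb / 6) / (ssw / 278)
  expect_equal(res$F, F_direct, tolerance = 1e-10)
  expect_equal(res$p, pf(F_direct, 6, 278, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_error(class_anova(v, rep("a", 6)), "two classes")
  expect_error(class_anova(1:3, c("a", "a", "b")), "at least two regions")
})
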