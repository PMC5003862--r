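test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_regions = 10, n_modules = 20),
               "n_modules > n_regions")
  expect_error(synthetic_config(p_in = 0.1, p_out = 0.5), "p_in")
  expect_error(synthetic_config(n_regions = 10, n_hubs = 10), "n_hubs")
  expect_error(synthetic_config(n_genes = 0), "positive count")
  expect_error(
    generate_expression(small_ds()$regions, small_ds()$metrics$mean,
                        small_cfg(n_genes = 100L,
                                  n_signal_genes_per_component = 60L)),
    "n_signal_genes_per_component")
  # noise-only configuration is a legal degenerate case
  expect_s3_class(synthetic_config(p_in = 0, p_out = 0, n_hubs = 0),
                  "synthetic_config")
})

test_that("region generation is deterministic and spatially modular", {
  cfg <- synthetic_config(n_regions = 40, n_modules = 4, seed = 1)
  a <- generate_regions(cfg)
  b <- generate_regions(cfg)
  expect_identical(a, b)
  expect_equal(as.vector(table(a$truth$module_labels)), rep(10L, 4))

  # mean within-module centroid distance < between, by brute force
  cfg2 <- synthetic_config(n_regions = 60, n_modules = 4, seed = 3)
  rg <- generate_regions(cfg2)
  D <- as.matrix(dist(rg$regions[, c("x", "y", "z")]))
  same <- outer(rg$truth$module_labels, rg$truth$module_labels, "==")
  ut <- upper.tri(D)
  expect_lt(mean(D[same & ut]), mean(D[!same & ut]))

  # single module: degenerate but legal
  rg1 <- generate_regions(synthetic_config(n_regions = 20, n_modules = 1,
                                           n_hubs = 2, seed = 2))
  expect_equal(unique(rg1$truth$module_labels), 1L)
})

test_that("planted blocks are spatially contiguous under single linkage", {
  rg <- generate_regions(synthetic_config(seed = 5))
  for (b in unique(rg$regions$block)) {
    xyz <- rg$regions[rg$regions$block == b, c("x", "y", "z")]
    hc <- hclust(dist(xyz), method = "single")
    # all members join below the generator's cluster diameter scale
    expect_lt(max(hc$height), 60)
  }
})

test_that("module coupling raises within-module correlation", {
  diffs <- vapply(1:20, function(s) {
    cfg_on <- synthetic_config(n_regions = 12, n_modules = 2, n_subjects = 1,
                               n_timepoints = 128, n_hubs = 0, p_in = 0.8,
                               p_out = 0, seed = s)
    cfg_off <- synthetic_config(n_regions = 12, n_modules = 2, n_subjects = 1,
                                n_timepoints = 128, n_hubs = 0, p_in = 0,
                                p_out = 0, seed = s)
    rg <- generate_regions(cfg_on)
    same_pair <- which(rg$truth$module_labels == 1)[1:2]
    r_of <- function(cfg) {
      ts <- generate_time_series(rg$regions, rg$truth, cfg)
      cor(ts$values[1, same_pair[1], ], ts$values[1, same_pair[2], ])
    }
    r_of(cfg_on) - r_of(cfg_off)
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.9)
  expect_gt(mean(diffs), 0.2)
})

test_that("hub regions correlate across module boundaries", {
  wins <- vapply(1:20, function(s) {
    cfg <- synthetic_config(n_regions = 40, n_modules = 4, n_subjects = 2,
                            n_timepoints = 128, n_hubs = 4, seed = s)
    rg <- generate_regions(cfg)
    ts <- generate_time_series(rg$regions, rg$truth, cfg)
    r <- cor(t(ts$values[1, , ]))
    mod <- rg$truth$module_labels
    hub <- rg$regions$region_id %in% rg$truth$hub_region_ids
    xmod_cor <- function(i) mean(abs(r[i, mod != mod[i]]))
    hub_x <- mean(vapply(which(hub), xmod_cor, numeric(1)))
    non_x <- mean(vapply(which(!hub), xmod_cor, numeric(1)))
    hub_x > non_x
  }, logical(1))
  expect_gt(mean(wins), 0.9)
})

test_that("noise-only configuration yields near-zero off-diagonal correlation", {
  cfg <- synthetic_config(n_regions = 30, n_subjects = 1, n_timepoints = 256,
                          p_in = 0, p_out = 0, n_hubs = 0,
                          distance_decay = 1e-6, seed = 11)
  rg <- generate_regions(cfg)
  ts <- generate_time_series(rg$regions, rg$truth, cfg)
  r <- cor(t(ts$values[1, , ]))
  off <- r[upper.tri(r)]
  expect_lt(abs(mean(off)), 0.03)
  expect_lt(max(abs(off)), 0.35)
})

test_that("time series length is validated", {
  cfg <- synthetic_config(n_timepoints = 16, n_regions = 20)
  rg <- generate_regions(cfg)
  expect_error(generate_time_series(rg$regions, rg$truth, cfg), "32")
})

test_that("expression generation is deterministic with planted structure", {
  ds <- small_ds()
  cfg <- ds$cfg
  a <- generate_expression(ds$regions, ds$metrics$mean, cfg)
  b <- generate_expression(ds$regions, ds$metrics$mean, cfg)
  expect_identical(a$expression, b$expression)
  # exactly K nonzero weights per component
  expect_equal(colSums(a$truth$gene_weights != 0),
               c(component1 = 80, component2 = 80))
  # planted terms draw from signal genes
  for (tm in a$truth$planted_term_ids) {
    comp <- if (grepl("c1", tm)) 1 else 2
    sig <- rownames(a$truth$gene_weights)[a$truth$gene_weights[, comp] != 0]
    expect_gt(mean(a$annotation[[tm]] %in% sig), 0.9)
  }
})

test_that("spatial noise field is autocorrelated; signal tracks k_intra", {
  ds <- small_ds()
  # effect_size = 0: pure noise field with positive Moran's I
  cfg0 <- small_cfg(seed = 21, effect_size = 0)
  rg <- generate_regions(cfg0)
  ex <- generate_expression(rg$regions, ds$metrics$mean[seq_len(60), ], cfg0)
  set.seed(1)
  mi <- vapply(sample(nrow(ex$expression), 20), function(g)
    oracle_moran(ex$expression[g, ], as.matrix(rg$regions[, c("x", "y", "z")])),
    numeric(1))
  expect_gt(mean(mi), 0)
  expect_gt(mean(mi > 0), 0.8)

  # signal genes of component 1 correlate positively with k_intra - z(d)
  hits <- vapply(1:20, function(s) {
    cfg <- small_cfg(seed = 100 + s)
    rg <- generate_regions(cfg)
    m <- small_ds()$metrics$mean
    ex <- generate_expression(rg$regions, m, cfg)
    w1 <- ex$truth$gene_weights[, 1]
    g <- which(w1 > 0)[1]
    p1 <- as.numeric(scale(scale(m$k_intra) - scale(m$d)))
    cor(ex$expression[g, ], p1) > 0
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("planted-partition graphs have the requested block structure", {
  pp <- planted_partition_graph(n_modules = 4, n_per_module = 10,
                                p_in = 0.9, p_out = 0.05, seed = 2)
  A <- pp$graph$adjacency
  expect_true(isSymmetric(A))
  expect_equal(unique(diag(A)), 0L)
  same <- outer(pp$labels, pp$labels, "==")
  ut <- upper.tri(A)
  expect_gt(mean(A[same & ut]), mean(A[!same & ut]))
})
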