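make_xy <- function(n = 40, p = 120, q = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("R%03d", 1:n), sprintf("G%04d", 1:p)))
  C <- matrix(rnorm(n * q), n, q,
              dimnames = list(rownames(X), c("k_intra", "k_inter", "d")))
  list(X = X, C = C, T = t(X))
}

test_that("a noiseless rank-1 response is fit by one component", {
  d <- make_xy(seed = 2)
  # responses proportional to a predictor-score direction that one
  # component can reproduce exactly (the exact-fit limit)
  z <- svd(d$X)$u[, 1]
  C1 <- cbind(a = z, b = 0.5 * z + 1, c = -2 * z)
  fit <- fit_pls(d$T, C1, n_components = 2)
  expect_gt(fit$cum_pct_variance[1], 99)
})

test_that("component 1 weights equal the dominant singular vector of cov(X, C)", {
  d <- make_xy(seed = 3)
  fit <- fit_pls(d$T, d$C, n_components = 3)
  sv <- svd(crossprod(d$X, scale(d$C)))
  cos_sim <- abs(sum(fit$weights[, 1] * sv$u[, 1]))
  expect_gt(cos_sim, 0.999)
})

test_that("components agree with an independent PLS implementation", {
  d <- make_xy(n = 40, p = 120, seed = 9)
  X <- scale(d$X)
  fit <- fit_pls(t(X), d$C, 2)
  mo <- mixOmics::pls(X, scale(d$C), ncomp = 2, mode = "regression",
                      scale = FALSE)
  for (a in 1:2) {
    w <- mo$loadings$X[, a]
    expect_gt(abs(sum(fit$weights[, a] * w)) / sqrt(sum(w^2)), 0.999)
  }
})

test_that("variance accounting is non-decreasing and exact at the limit", {
  d <- make_xy(n = 20, p = 50, seed = 4)
  fit <- fit_pls(d$T, d$C, n_components = 20)
  expect_true(all(diff(fit$cum_pct_variance) >= -1e-10))
  expect_true(all(fit$pct_variance >= -1e-10))
  expect_equal(unname(max(fit$cum_pct_variance)), 100, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with named offenders", {
  d <- make_xy()
  Cbad <- d$C; Cbad[, 2] <- 7
  expect_error(fit_pls(d$T, Cbad, 2), "k_inter")
  expect_error(fit_pls(d$T, d$C, n_components = 99), "exceeds")
  expect_error(fit_pls(d$T[, 1:10], d$C, 2), "regions")
})

test_that("sign orientation flips with the planted pattern, |r| does not", {
  set.seed(5)
  n <- 50; p <- 200
  pattern <- rnorm(n)
  w <- rep(0, p); w[1:20] <- 1
  noise <- matrix(rnorm(p * n), p, n)
  Tm <- 2 * w %o% pattern + noise
  rownames(Tm) <- sprintf("G%04d", 1:p); colnames(Tm) <- sprintf("R%03d", 1:n)
  C <- cbind(k_intra = pattern + rnorm(n, sd = .3),
             k_inter = rnorm(n), d = rnorm(n))
  f1 <- fit_pls(Tm, C, 2)
  Tm2 <- 2 * w %o% (-pattern) + noise
  dimnames(Tm2) <- dimnames(Tm)
  C2 <- cbind(k_intra = -pattern + rnorm(n, sd = .3),
              k_inter = rnorm(n), d = rnorm(n))
  f2 <- fit_pls(Tm2, C2, 2)
  expect_equal(abs(cor(f1$weights[, 1], w)), abs(cor(f2$weights[, 1], w)),
               tolerance = 0.05)
  # orientation makes the dominant response correlation positive
  expect_gt(f1$response_cor[1, "k_intra"], 0)
  expect_gt(f2$response_cor[1, "k_intra"], 0)
})

test_that("metric correlations match the textbook Pearson formula", {
  ds <- small_ds()
  Tz <- zscore_expression(ds$expression)
  fit <- fit_pls(Tz, ds$metrics$C, 2)
  coords <- as.matrix(ds$regions[, c("x", "y", "z")])
  mc <- metric_correlations(fit, ds$metrics$mean, coords)
  expect_setequal(unique(mc$variable),
                  c("k", "PC", "k_intra", "k_inter", "d", "abs_x", "y", "z"))
  direct_r <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  row <- mc[mc$component == "PLS1" & mc$variable == "d", ]
  expect_equal(row$r, direct_r(fit$scores[, 1], ds$metrics$mean$d),
               tolerance = 1e-12)
  row2 <- mc[mc$component == "PLS2" & mc$variable == "abs_x", ]
  expect_equal(row2$r, direct_r(fit$scores[, 2], abs(coords[, 1])),
               tolerance = 1e-12)
  # scores identical to a metric give r = 1
  fit2 <- fit
  fit2$scores[, 1] <- ds$metrics$mean$k_intra
  mc2 <- metric_correlations(fit2, ds$metrics$mean, coords)
  expect_equal(mc2[mc2$component == "PLS1" & mc2$variable == "k_intra", "r"],
               1, tolerance = 1e-12)
})

test_that("planted components correlate with the expected metric signs", {
  hits <- vapply(1:10, function(s) {
    cfg <- small_cfg(seed = 300 + s, n_regions = 120L, n_modules = 8L,
                     n_genes = 1500L, n_signal_genes_per_component = 300L)
    ds <- synth_dataset(cfg, n_runs = 15)
    Tz <- zscore_expression(ds$expression)
    fit <- fit_pls(Tz, ds$metrics$C, 2)
    rc <- cor(fit$weights, ds$truth$gene_weights)
    c1 <- which.max(abs(rc[, 1])); s1 <- sign(rc[c1, 1])
    c2 <- which.max(abs(rc[, 2])); s2 <- sign(rc[c2, 2])
    mcor <- fit$response_cor
    ok1 <- (s1 * mcor[c1, "k_intra"] > 0) && (s1 * mcor[c1, "d"] < 0)
    ok2 <- (s2 * mcor[c2, "k_inter"] > 0) && (s2 * mcor[c2, "d"] > 0)
    ok1 && ok2 && (c1 != c2)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("bootstrap ranking is deterministic and centred under the null", {
  d <- make_xy(n = 30, p = 60, seed = 6)
  r1 <- bootstrap_ranking(d$T, d$C, component = 1, n_boot = 100, seed = 3)
  r2 <- bootstrap_ranking(d$T, d$C, component = 1, n_boot = 100, seed = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$se > 0))
  expect_setequal(r1$rank, seq_len(60))
  expect_error(bootstrap_ranking(d$T, d$C, n_boot = 10), "100")

  # a pure-noise gene's Z is centred near 0 across replicates
  zs <- vapply(1:50, function(s) {
    dd <- make_xy(n = 30, p = 40, seed = 100 + s)
    rk <- bootstrap_ranking(dd$T, dd$C, component = 1, n_boot = 100, seed = s)
    rk$z[rk$gene == "G0001"]
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.3)
})

test_that("permutation p-values are valid and the block scheme reduces to naive", {
  d <- make_xy(n = 30, p = 50, seed = 7)
  pt <- permutation_test(d$T, d$C, n_components = 2, n_perm = 99, seed = 1)
  expect_gte(pt$p, 1 / 100)
  expect_lte(pt$p, 1)
  expect_length(pt$null, 99)

  # singleton blocks reproduce the naive null exactly (same seed stream)
  ptb <- permutation_test(d$T, d$C, n_components = 2, n_perm = 99, seed = 1,
                          scheme = "block", blocks = seq_len(30))
  expect_equal(pt$null, ptb$null)
  expect_equal(pt$p, ptb$p)

  expect_error(permutation_test(d$T, d$C, 2, 9, scheme = "block",
                                blocks = rep(1, 30)), "one block")
  expect_error(permutation_test(d$T, d$C, 2, 9, scheme = "block",
                                blocks = 1:4), "cover")
})

test_that("planted association is detected at the minimal p-value", {
  cfg <- small_cfg(seed = 33)
  ds <- synth_dataset(cfg, n_runs = 15)
  Tz <- zscore_expression(ds$expression)
  pt <- permutation_test(Tz, ds$metrics$C, n_components = 2, n_perm = 99,
                         seed = 2)
  expect_equal(pt$p, 1 / 100)
})
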