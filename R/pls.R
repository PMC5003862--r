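# Core PLS2 engine on pre-scaled blocks. X: n x p, Y: n x q. Per component
# the weight vector is the dominant left singular vector of the
# cross-covariance X'Y -- the fixed point of the NIPALS inner iteration --
# computed exactly from the q x q eigenproblem of (X'Y)'(X'Y), followed by
# the usual predictor- and response-block deflation. Returns weights W
# (p x A), scores Tm (n x A), x-loadings P, y-loadings Q, and per-component
# explained response sum of squares.
nipals_pls2 <- function(X, Y, A) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Tm <- matrix(0, n, A); Qm <- matrix(0, q, A)
  ssy <- numeric(A)
  Xc <- X; Yc <- Y
  for (a in seq_len(A)) {
    Z <- crossprod(Xc, Yc)                 # p x q
    w <- if (q == 1L) Z
         else Z %*% eigen(crossprod(Z), symmetric = TRUE)$vectors[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) break
    w <- w / nw
    tt <- Xc %*% w
    tq <- sum(tt^2)
    if (tq < 1e-300) break
    qv <- crossprod(Yc, tt) / tq
    pv <- crossprod(Xc, tt) / tq
    W[, a] <- w; Tm[, a] <- tt; P[, a] <- pv; Qm[, a] <- qv
    ssy[a] <- tq * sum(qv^2)               # ||t q'||_F^2
    Xc <- Xc - tcrossprod(tt, pv)
    Yc <- Yc - tcrossprod(tt, qv)
  }
  list(W = W, P = P, T = Tm, Q = Qm, ss_response = ssy)
}

# Fast path used by permutation tests: cumulative % response variance
# explained by the first A components.
pls_cum_pct_var <- function(X, Y, A) {
  fit <- nipals_pls2(X, Y, A)
  100 * sum(fit$ss_response) / sum(Y^2)
}

#' Partial least squares regression of nodal metrics on gene expression
#'
#' Multi-response PLS (PLS2, NIPALS with predictor- and response-block
#' deflation): components are gene-expression combinations with maximal
#' covariance with the response block of nodal network metrics. Response
#' columns are standardized before fitting (they carry incommensurate
#' units); predictors are expected to be gene-wise Z-scored already. Each
#' component is sign-oriented so that the response variable with the
#' largest-|r| correlation to its region scores correlates positively
#' (ties broken by response column order).
#'
#' @param T gene x region Z-scored expression matrix (predictor block; its
#'   transpose is used as the regions x genes design matrix), or a
#'   regions x genes matrix if `predictors_in_rows = FALSE`.
#' @param C regions x responses matrix of nodal metrics (typically the
#'   columns k_intra, k_inter, d).
#' @param n_components number of components (<= number of regions).
#' @param scale_response standardize response columns (default TRUE).
#' @param predictors_in_rows `TRUE` (default) when `T` is genes x regions.
#' @return A `pls_fit` object: `weights` (genes x A), `scores` (regions x
#'   A), `y_loadings`, `x_loadings`, `pct_variance` (% of total response
#'   variance per component), `cum_pct_variance`, `response_cor`
#'   (component scores vs response columns), plus the call metadata.
#' @export
fit_pls <- function(T, C, n_components = 3L, scale_response = TRUE,
                    predictors_in_rows = TRUE) {
  X <- if (predictors_in_rows) t(T) else T
  C <- as.matrix(C)
  if (nrow(X) != nrow(C))
    stop("T and C disagree on the number of regions")
  if (n_components > nrow(X))
    stop("n_components exceeds the number of regions")
  sds <- apply(C, 2, sd)
  if (any(sds == 0))
    stop("constant response column: ",
         paste(colnames(C)[sds == 0], collapse = ", "))
  Y <- if (scale_response) scale(C) else scale(C, scale = FALSE)
  Y <- matrix(as.numeric(Y), nrow(Y), ncol(Y),
              dimnames = list(rownames(C), colnames(C)))
  fit <- nipals_pls2(X, Y, n_components)
  # sign orientation
  for (a in seq_len(n_components)) {
    rr <- suppressWarnings(cor(fit$T[, a], Y))
    j <- which.max(round(abs(rr), 12))      # ties -> earlier column
    if (rr[j] < 0) {
      fit$W[, a] <- -fit$W[, a]; fit$T[, a] <- -fit$T[, a]
      fit$P[, a] <- -fit$P[, a]; fit$Q[, a] <- -fit$Q[, a]
    }
  }
  pct <- 100 * fit$ss_response / sum(Y^2)
  comp_names <- paste0("PLS", seq_len(n_components))
  dimnames(fit$W) <- list(colnames(X), comp_names)
  dimnames(fit$T) <- list(rownames(X), comp_names)
  dimnames(fit$Q) <- list(colnames(C), comp_names)
  response_cor <- suppressWarnings(cor(fit$T, Y))
  structure(list(
    weights = fit$W, scores = fit$T, x_loadings = fit$P,
    y_loadings = fit$Q, pct_variance = setNames(pct, comp_names),
    cum_pct_variance = setNames(cumsum(pct), comp_names),
    response_cor = response_cor, n_components = n_components,
    n_regions = nrow(X), n_genes = ncol(X),
    response_names = colnames(C), scale_response = scale_response
  ), class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("pls_fit: %d components, %d regions x %d genes\n",
              x$n_components, x$n_regions, x$n_genes))
  cat("% response variance:",
      paste(sprintf("%s %.1f", names(x$pct_variance), x$pct_variance),
            collapse = ", "),
      sprintf("(cumulative %.1f)\n", max(x$cum_pct_variance)))
  invisible(x)
}

#' @export
summary.pls_fit <- function(object, ...) {
  print(object)
  cat("\nComponent-response correlations:\n")
  print(round(object$response_cor, 3))
  invisible(object)
}

#' @export
coef.pls_fit <- function(object, component = NULL, ...) {
  if (is.null(component)) object$weights
  else object$weights[, component]
}

#' Project new expression data onto fitted PLS components
#'
#' @param object a `pls_fit`.
#' @param newdata gene x region matrix on the same genes (or regions x
#'   genes with `predictors_in_rows = FALSE`).
#' @param predictors_in_rows orientation of `newdata`.
#' @param ... unused.
#' @return regions x components score matrix.
#' @export
predict.pls_fit <- function(object, newdata, predictors_in_rows = TRUE, ...) {
  X <- if (predictors_in_rows) t(newdata) else newdata
  if (ncol(X) != nrow(object$weights)) stop("gene set mismatch")
  # scores via the weight rotation R = W (P'W)^-1
  R <- object$weights %*% solve(crossprod(object$x_loadings, object$weights))
  X %*% R
}

#' Correlations of PLS region scores with nodal metrics and coordinates
#'
#' Pearson correlation (with two-sided p-values) of each component's region
#' scores against total degree, participation coefficient, intra- and
#' inter-modular degree, connection distance, and the spatial coordinates
#' |x|, y, z.
#'
#' @param fit a `pls_fit`.
#' @param metrics a `nodal_metrics` data.frame aligned to the fit's
#'   regions.
#' @param coords n x 3 centroid matrix (columns x, y, z).
#' @return data.frame with one row per component x variable: component,
#'   variable, r, p.
#' @export
metric_correlations <- function(fit, metrics, coords = NULL) {
  vars <- list(k = metrics$k, PC = metrics$pc, k_intra = metrics$k_intra,
               k_inter = metrics$k_inter, d = metrics$d)
  if (!is.null(coords)) {
    vars$abs_x <- abs(coords[, 1]); vars$y <- coords[, 2]
    vars$z <- coords[, 3]
  }
  out <- do.call(rbind, lapply(colnames(fit$scores), function(comp) {
    do.call(rbind, lapply(names(vars), function(v) {
      ok <- stats::complete.cases(fit$scores[, comp], vars[[v]])
      ct <- cor.test(fit$scores[ok, comp], vars[[v]][ok])
      data.frame(component = comp, variable = v,
                 r = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Bootstrap gene ranking for a PLS component
#'
#' Regions are resampled with replacement `n_boot` times; the PLS model is
#' refit on each resample and the drawn component's weight vector is
#' sign-aligned to the original fit (by the sign of their inner product).
#' The bootstrap standard error of each gene's weight yields
#' `Z = weight / SE`, and genes are ranked by descending Z.
#'
#' @param T gene x region Z-scored expression matrix.
#' @param C regions x responses metric matrix.
#' @param component which component to rank genes on.
#' @param n_boot number of bootstrap draws (>= 100 for stable SEs).
#' @param seed RNG seed.
#' @param fit optional pre-computed `pls_fit` on (T, C).
#' @return A `gene_ranking` data.frame: gene, weight, se, z, rank (1 = most
#'   positive Z), with attributes `component`, `n_boot`, `seed`.
#' @export
bootstrap_ranking <- function(T, C, component = 1L, n_boot = 1000L,
                              seed = 1L, fit = NULL) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  C <- as.matrix(C)
  X <- t(T)
  n <- nrow(X)
  if (is.null(fit)) fit <- fit_pls(T, C, n_components = component)
  w0 <- fit$weights[, component]
  acc <- matrix(0, length(w0), n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (try in seq_len(50L)) {
        idx <- sample(n, n, replace = TRUE)
        if (length(unique(idx)) >= 2L &&
            all(apply(C[idx, , drop = FALSE], 2, sd) > 0)) break
      }
      Yb <- scale(C[idx, , drop = FALSE])
      fb <- nipals_pls2(X[idx, , drop = FALSE], Yb, component)
      wb <- fb$W[, component]
      if (sum(wb * w0) < 0) wb <- -wb
      acc[, b] <- wb
    }
  })
  se <- apply(acc, 1, sd)
  z <- w0 / se
  out <- data.frame(gene = rownames(fit$weights) %||% gene_ids_for(length(w0)),
                    weight = w0, se = se, z = z,
                    rank = rank(-z, ties.method = "first"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "component") <- component
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  class(out) <- c("gene_ranking", "data.frame")
  out
}

# Block-respecting row permutation: blocks are shuffled as units (random
# block order, within-block region order preserved) and regions re-assigned
# to the concatenated positions. With every block a singleton this is a
# uniform permutation, so the naive scheme is the singleton-block special
# case and shares its seed stream.
block_permute_order <- function(blocks) {
  idx <- split(seq_along(blocks), factor(blocks, levels = unique(blocks)))
  if (length(idx) < 2L) stop("block permutation requires more than one block")
  unlist(idx[sample(length(idx))], use.names = FALSE)
}

#' Permutation test of the PLS goodness of fit
#'
#' The observed statistic is the cumulative percentage of response variance
#' explained by the first `n_components` PLS components. The null is built
#' by re-fitting after permuting the rows of `C` as whole metric vectors:
#' the `naive` scheme permutes regions freely; the `block` scheme permutes
#' spatially contiguous blocks of regions as units, respecting spatial
#' autocorrelation. P-values use the add-one estimator
#' `(1 + #{null >= obs}) / (1 + n_perm)` and never return 0.
#'
#' @param T gene x region expression matrix.
#' @param C regions x responses metric matrix.
#' @param n_components components entering the statistic.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param scheme `"naive"` or `"block"`.
#' @param blocks region block labels (required for `scheme = "block"`;
#'   if `NULL`, blocks are built by k-means on `coords` with
#'   `round(n/10)` clusters).
#' @param coords optional centroids for k-means block construction.
#' @return A `perm_test` list: `observed`, `null` (length `n_perm`), `p`,
#'   `scheme`, `n_perm`, `seed`.
#' @export
permutation_test <- function(T, C, n_components = 3L, n_perm = 1000L,
                             seed = 1L, scheme = c("naive", "block"),
                             blocks = NULL, coords = NULL) {
  scheme <- match.arg(scheme)
  C <- as.matrix(C)
  X <- t(T)
  n <- nrow(X)
  if (scheme == "block") {
    if (is.null(blocks)) {
      if (is.null(coords))
        stop("block scheme requires block labels or coords")
      blocks <- with_seed(derive_seed(seed, 99L),
                          kmeans(coords, centers = max(2L, round(n / 10)),
                                 nstart = 5)$cluster)
    }
    if (length(blocks) != n)
      stop("block labels must cover all regions")
  } else {
    blocks <- seq_len(n)
  }
  Y <- scale(C)
  observed <- pls_cum_pct_var(X, Y, n_components)
  null <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      ord <- block_permute_order(blocks)
      null[b] <- pls_cum_pct_var(X, Y[ord, , drop = FALSE], n_components)
    }
  })
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null = null, p = p, scheme = scheme,
                 n_perm = n_perm, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "perm_test (%s): observed = %.2f%%, p = %.4g (%d permutations)\n",
    x$scheme, x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Calibration of naive vs block permutation schemes under spatial noise
#'
#' Monte-Carlo study of type-I error: each simulated dataset has spatially
#' autocorrelated expression and spatially autocorrelated but independent
#' nodal metrics (no true association), and both permutation schemes are
#' run at level `alpha`. Under spatial autocorrelation the naive scheme is
#' expected to reject too often; the report flags that inflation when the
#' naive rate exceeds the binomial 95% upper bound of `alpha`.
#'
#' @param cfg a [synthetic_config()]; `n_regions`, `n_genes`,
#'   `spatial_corr_length` and `seed` are used. Keep the sizes small: the
#'   study fits `2 * n_sims * (n_perm + 1)` PLS models.
#' @param n_sims number of null simulations.
#' @param n_perm permutations per test.
#' @param alpha nominal level.
#' @param n_components components entering the test statistic.
#' @return list with `naive_rate`, `block_rate`, binomial 95% CI for
#'   `alpha`, `naive_inflated` flag, and the per-sim p-values.
#' @export
spatial_calibration_check <- function(cfg, n_sims = 200L, n_perm = 199L,
                                      alpha = 0.05, n_components = 2L) {
  rg <- generate_regions(cfg)
  coords <- as.matrix(rg$regions[, c("x", "y", "z")])
  n <- cfg$n_regions
  L <- diag(n)
  if (cfg$spatial_corr_length > 0) {
    D <- as.matrix(dist(coords))
    L <- exp(-D / cfg$spatial_corr_length)
    L <- L / sqrt(rowSums(L^2))
  }
  p_naive <- numeric(n_sims); p_block <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    sseed <- derive_seed(cfg$seed, 10000L + s)
    dat <- with_seed(sseed, {
      Tm <- matrix(rnorm(cfg$n_genes * n), cfg$n_genes, n) %*% t(L)
      Cm <- t(L %*% matrix(rnorm(n * 3), n, 3))
      list(T = Tm, C = t(Cm))
    })
    p_naive[s] <- permutation_test(dat$T, dat$C, n_components, n_perm,
                                   seed = derive_seed(sseed, 1L),
                                   scheme = "naive")$p
    p_block[s] <- permutation_test(dat$T, dat$C, n_components, n_perm,
                                   seed = derive_seed(sseed, 2L),
                                   scheme = "block",
                                   blocks = rg$truth$block_labels)$p
  }
  ci <- alpha + c(-1.96, 1.96) * sqrt(alpha * (1 - alpha) / n_sims)
  naive_rate <- mean(p_naive <= alpha)
  block_rate <- mean(p_block <= alpha)
  list(naive_rate = naive_rate, block_rate = block_rate,
       alpha = alpha, ci = ci,
       naive_inflated = naive_rate > ci[2],
       p_naive = p_naive, p_block = p_block)
}
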