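# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small but complete synthetic study (fast; used by many tests).
small_cfg <- function(seed = 7L, ...) {
  args <- utils::modifyList(
    list(n_regions = 60L, n_modules = 4L, n_subjects = 4L,
         n_timepoints = 128L, n_genes = 400L,
         n_signal_genes_per_component = 80L, n_terms = 20L,
         term_size = 20L, seed = seed),
    list(...))
  do.call(synthetic_config, args)
}

small_ds <- function() {
  cached("small_ds", function() synth_dataset(small_cfg(), n_runs = 25L))
}

# Random connected binary graph with coordinates, for metric oracles.
random_graph <- function(n, density = 0.15, seed = 1L) {
  set.seed(seed)
  r <- matrix(runif(n * n, -1, 1), n)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  coords <- matrix(runif(n * 3, 0, 100), n)
  build_graph(r, density = density, coords = coords)
}

# Brute-force nodal metric oracle: per-node loop over edges.
oracle_nodal <- function(A, labels, coords) {
  n <- nrow(A)
  out <- data.frame(k = numeric(n), k_intra = numeric(n),
                    k_inter = numeric(n), pc = numeric(n), d = numeric(n))
  M <- max(labels)
  for (i in seq_len(n)) {
    nbr <- which(A[i, ] == 1)
    out$k[i] <- length(nbr)
    out$k_intra[i] <- sum(labels[nbr] == labels[i])
    out$k_inter[i] <- sum(labels[nbr] != labels[i])
    if (length(nbr) == 0) {
      out$pc[i] <- NA; out$d[i] <- NA
    } else {
      kim <- vapply(seq_len(M), function(m) sum(labels[nbr] == m), numeric(1))
      out$pc[i] <- 1 - sum((kim / length(nbr))^2)
      out$d[i] <- mean(sqrt(rowSums(
        (coords[nbr, , drop = FALSE] -
         matrix(coords[i, ], length(nbr), 3, byrow = TRUE))^2)))
    }
  }
  out
}

# Brute-force modularity at resolution gamma (double-sum definition).
oracle_modularity <- function(A, labels, gamma = 1) {
  k <- rowSums(A)
  m2 <- sum(k)
  same <- outer(labels, labels, "==")
  sum((A - gamma * outer(k, k) / m2) * same) / m2
}

# Adjusted Rand index (mclust) -- used against generator ground truth.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Moran's I by the direct double sum with inverse-distance weights.
oracle_moran <- function(values, coords) {
  n <- length(values)
  D <- as.matrix(dist(coords))
  W <- 1 / D; diag(W) <- 0
  zc <- values - mean(values)
  (n / sum(W)) * sum(W * outer(zc, zc)) / sum(zc^2)
}
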