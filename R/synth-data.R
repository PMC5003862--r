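#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic study: a spatially embedded modular
#' network with designated inter-modular hubs, matching multi-subject time
#' series, and a gene-expression matrix carrying two planted low-rank
#' components tied to the network's nodal metrics, plus GMT annotations with
#' planted enriched terms.
#'
#' @param n_regions number of cortical regions (network nodes).
#' @param n_modules number of planted modules (>= 2 for a modular network;
#'   1 is allowed as a degenerate case).
#' @param n_subjects number of simulated subjects.
#' @param n_timepoints time series length per subject (>= 32).
#' @param tr_seconds sampling interval in seconds.
#' @param p_in,p_out intra-/inter-module coupling strengths (unitless, 0-1;
#'   `p_in > p_out` required).
#' @param n_hubs number of designated inter-modular hub regions.
#' @param distance_decay length scale (mm) of distance-dependent local
#'   coupling between nearby regions.
#' @param n_genes number of genes.
#' @param n_signal_genes_per_component number of genes carrying each planted
#'   expression component. The default (1000, i.e. 20% of the default
#'   genome) reflects the breadth of dominant cortical expression gradients
#'   and keeps the planted weights identifiable: a component carried by K of
#'   p genes over n regions cannot be recovered beyond
#'   |r| = sqrt(nK / (nK + p - K)) at any signal strength.
#' @param effect_size per-gene signal-to-noise ratio of the first planted
#'   component (per-gene signal standard deviation over noise standard
#'   deviation); the second component's amplitude is 0.3x the first,
#'   mirroring the dominance of the leading transcriptional gradient.
#' @param spatial_corr_length length scale (mm) of the spatially
#'   autocorrelated expression noise field (0 = white noise).
#' @param n_terms,term_size number and size of synthetic annotation terms.
#' @param seed RNG seed; all generator outputs are pure functions of the
#'   configuration including this seed.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_regions = 200L, n_modules = 8L,
                             n_subjects = 10L, n_timepoints = 256L,
                             tr_seconds = 2.42, p_in = 0.8, p_out = 0.1,
                             n_hubs = 16L, distance_decay = 20,
                             n_genes = 5000L,
                             n_signal_genes_per_component = 1000L,
                             effect_size = 2, spatial_corr_length = 20,
                             n_terms = 50L, term_size = 40L, seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions), n_modules = as.integer(n_modules),
    n_subjects = as.integer(n_subjects),
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, p_in = p_in, p_out = p_out,
    n_hubs = as.integer(n_hubs), distance_decay = distance_decay,
    n_genes = as.integer(n_genes),
    n_signal_genes_per_component = as.integer(n_signal_genes_per_component),
    effect_size = effect_size, spatial_corr_length = spatial_corr_length,
    n_terms = as.integer(n_terms), term_size = as.integer(term_size),
    seed = as.integer(seed)
  )
  counts <- c("n_regions", "n_modules", "n_subjects", "n_timepoints",
              "n_genes", "n_terms", "term_size")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("invalid config: `", f, "` must be a positive count")
  }
  if (cfg$n_modules > cfg$n_regions)
    stop("invalid config: n_modules > n_regions")
  if (cfg$n_hubs < 0L || cfg$n_hubs >= cfg$n_regions)
    stop("invalid config: n_hubs must satisfy 0 <= n_hubs < n_regions")
  if (!(cfg$p_in > cfg$p_out || (cfg$p_in == 0 && cfg$p_out == 0)))
    stop("invalid config: p_in must exceed p_out")
  if (cfg$n_signal_genes_per_component < 0L)
    stop("invalid config: n_signal_genes_per_component must be >= 0")
  class(cfg) <- "synthetic_config"
  cfg
}

region_ids_for <- function(n) sprintf("R%03d", seq_len(n))
gene_ids_for <- function(n) sprintf("G%05d", seq_len(n))

#' Generate a spatially embedded region table with planted modules
#'
#' Regions are placed as isotropic Gaussian clusters of centroids (cluster
#' s.d. 10 mm) around module centres sampled in a 150 mm box with a
#' minimum-separation rule, roughly brain-scale. Module membership therefore
#' coincides with spatial clustering, producing the distance/modularity
#' confound that motivates spatially constrained permutation nulls. The
#' spatial clusters are also emitted as contiguous block labels for the
#' block permutation scheme, and a cytoarchitectonic-class-like label is
#' derived from the module id.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with `regions` (data.frame: region_id, x, y, z, class,
#'   block) and `truth` (module labels, hub region ids, block labels).
#' @export
generate_regions <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(derive_seed(cfg$seed, 1L), {
    M <- cfg$n_modules
    box <- c(15, 135)
    min_sep <- if (M > 1L) 45 else 0
    centers <- NULL
    best <- NULL; best_sep <- -Inf
    for (try in seq_len(500L)) {
      cand <- matrix(runif(M * 3, box[1], box[2]), ncol = 3)
      sep <- if (M > 1L) min(dist(cand)) else Inf
      if (sep > best_sep) { best <- cand; best_sep <- sep }
      if (sep >= min_sep) { centers <- cand; break }
    }
    if (is.null(centers)) centers <- best
    sizes <- rep(cfg$n_regions %/% M, M)
    if (cfg$n_regions %% M > 0L)
      sizes[seq_len(cfg$n_regions %% M)] <- sizes[seq_len(cfg$n_regions %% M)] + 1L
    module_labels <- rep(seq_len(M), times = sizes)
    xyz <- centers[module_labels, , drop = FALSE] +
      matrix(rnorm(cfg$n_regions * 3, sd = 10), ncol = 3)
    # hubs spread across modules round-robin, chosen at random within module
    hub_ids <- integer(0)
    if (cfg$n_hubs > 0L) {
      per_mod <- split(seq_len(cfg$n_regions), module_labels)
      ord <- rep(seq_len(M), length.out = cfg$n_hubs)
      taken <- lapply(per_mod, function(ix) sample(ix))
      cnt <- integer(M)
      for (m in ord) {
        cnt[m] <- cnt[m] + 1L
        if (cnt[m] <= length(taken[[m]])) hub_ids <- c(hub_ids, taken[[m]][cnt[m]])
      }
      hub_ids <- sort(hub_ids)
    }
    ids <- region_ids_for(cfg$n_regions)
    regions <- data.frame(
      region_id = ids,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      class = ((module_labels - 1L) %% 7L) + 1L,
      block = module_labels,
      stringsAsFactors = FALSE
    )
    truth <- list(
      module_labels = module_labels,
      hub_region_ids = ids[hub_ids],
      block_labels = module_labels
    )
    list(regions = regions, truth = truth)
  })
}

#' Generate multi-subject regional time series with modular correlation
#'
#' Each region's signal is the sum of its module's shared factor (weight
#' `p_in`), a global factor (weight `p_out`), distance-decaying local
#' coupling (a spatially smoothed noise field), and independent unit noise.
#' Designated hub regions additionally load on every other module's factor,
#' so they correlate across module boundaries. The structured part of every
#' region's signal is scaled by a region-specific coupling amplitude drawn
#' uniformly on 0.4-1.6 (fixed per region across subjects), emulating the
#' broad degree distribution of real functional networks: strongly coupled
#' regions acquire both more intra- and more inter-modular edges in the
#' thresholded graph.
#'
#' @param regions region table from [generate_regions()].
#' @param truth ground truth from [generate_regions()].
#' @param cfg a [synthetic_config()].
#' @return A `time_series_set`: list with `values` (subjects x regions x
#'   timepoints array), `tr_seconds`, `region_ids`.
#' @export
generate_time_series <- function(regions, truth, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_timepoints < 32L)
    stop("n_timepoints < 32: too short for scale-3 wavelet correlation")
  n <- nrow(regions)
  if (length(truth$module_labels) != n)
    stop("regions and truth are inconsistent")
  M <- cfg$n_modules
  tp <- cfg$n_timepoints
  mod <- truth$module_labels
  hub_idx <- match(truth$hub_region_ids, regions$region_id)
  D <- as.matrix(dist(regions[, c("x", "y", "z")]))
  # local-coupling mixing matrix: rows normalised to unit Euclidean norm so
  # the smoothed field keeps unit variance
  W <- exp(-D / max(cfg$distance_decay, 1e-8))
  W <- W / sqrt(rowSums(W^2))
  hub_w <- if (M > 1L) 0.6 * cfg$p_in / sqrt(M - 1L) else 0
  vals <- array(0, dim = c(cfg$n_subjects, n, tp))
  with_seed(derive_seed(cfg$seed, 2L), {
    amp <- runif(n, 0.4, 1.6)     # per-region coupling amplitude
    for (s in seq_len(cfg$n_subjects)) {
      Fm <- matrix(rnorm(tp * M), tp, M)       # module factors
      G <- rnorm(tp)                           # weak global factor
      local <- W %*% matrix(rnorm(n * tp), n, tp)
      X <- t(Fm[, mod, drop = FALSE]) * cfg$p_in +
        matrix(G, n, tp, byrow = TRUE) * cfg$p_out +
        0.3 * local
      if (length(hub_idx) > 0L && M > 1L) {
        for (h in hub_idx) {
          others <- setdiff(seq_len(M), mod[h])
          X[h, ] <- X[h, ] + hub_w * rowSums(Fm[, others, drop = FALSE])
        }
      }
      vals[s, , ] <- amp * X + matrix(rnorm(n * tp), n, tp)
    }
  })
  structure(
    list(values = vals, tr_seconds = cfg$tr_seconds,
         region_ids = regions$region_id),
    class = "time_series_set"
  )
}

# Relative amplitudes of the two planted expression components: the leading
# transcriptional gradient dominates, which also keeps the two planted
# weight vectors identifiable as separate PLS components (see vignette).
component_amplitudes <- c(1, 0.3)

#' Plant low-rank expression components tied to nodal network metrics
#'
#' The expression matrix (genes x regions) is
#' `sum_c a_c * w_c %o% pattern_c + noise`, where `pattern_1` is the
#' standardized contrast `z(k_intra) - z(d)` and `pattern_2` is
#' `z(k_inter) + z(d)` (each re-standardized to unit variance), `w_c` is a
#' sparse non-negative gene-weight vector (magnitudes uniform on 0.5-1.5;
#' each planted program is coherently co-upregulated with its regional
#' pattern) and the noise is a unit-variance Gaussian field with spatial
#' autocorrelation length `spatial_corr_length`. Component amplitudes are
#' `effect_size * c(1, 0.45)` per-gene signal-to-noise. Synthetic GMT
#' annotations are drawn with planted terms concentrated in signal genes.
#'
#' @param regions region table from [generate_regions()].
#' @param metrics a `nodal_metrics` data.frame (from [nodal_metrics()] or
#'   the mean slot of [nodal_metrics_set()]) computed on the synthetic
#'   network; must contain columns `k_intra`, `k_inter`, `d`.
#' @param cfg a [synthetic_config()].
#' @param truth ground truth list to update.
#' @return A list: `expression` (genes x regions matrix, raw scale),
#'   `truth` (updated with per-gene `gene_weights` matrix and
#'   `planted_term_ids`), `annotation` (named list of gene vectors, GMT
#'   style), `gene_sets` (the two planted components' signal genes as
#'   candidate sets).
#' @export
generate_expression <- function(regions, metrics, cfg, truth = list()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  K <- cfg$n_signal_genes_per_component
  if (2L * K > cfg$n_genes)
    stop("invalid config: 2 * n_signal_genes_per_component > n_genes")
  need <- c("k_intra", "k_inter", "d")
  if (!all(need %in% names(metrics)))
    stop("metrics must contain columns k_intra, k_inter, d")
  n <- nrow(regions)
  stopifnot(nrow(metrics) == n)
  z <- function(v) as.numeric(scale(v))
  p1 <- z(z(metrics$k_intra) - z(metrics$d))
  p2 <- z(z(metrics$k_inter) + z(metrics$d))
  patterns <- cbind(p1, p2)
  amps <- cfg$effect_size * component_amplitudes
  genes <- gene_ids_for(cfg$n_genes)
  with_seed(derive_seed(cfg$seed, 3L), {
    sig_idx <- if (K > 0L) matrix(sample(cfg$n_genes, 2L * K), ncol = 2L)
               else matrix(integer(0), ncol = 2L)
    gene_weights <- matrix(0, cfg$n_genes, 2L,
                           dimnames = list(genes, c("component1", "component2")))
    for (c_i in 1:2) {
      if (K > 0L) {
        # one-signed weights: each planted program is a coherently
        # co-upregulated gene set, so signal genes rank at one list end
        gene_weights[sig_idx[, c_i], c_i] <- runif(K, 0.5, 1.5)
      }
    }
    signal <- amps[1] * gene_weights[, 1, drop = FALSE] %*% t(p1) +
      amps[2] * gene_weights[, 2, drop = FALSE] %*% t(p2)
    noise <- matrix(rnorm(cfg$n_genes * n), cfg$n_genes, n)
    if (cfg$spatial_corr_length > 0) {
      D <- as.matrix(dist(regions[, c("x", "y", "z")]))
      L <- exp(-D / cfg$spatial_corr_length)
      L <- L / sqrt(rowSums(L^2))
      noise <- noise %*% t(L)
    }
    expr <- signal + noise
    dimnames(expr) <- list(genes, regions$region_id)
    # annotations: planted terms concentrated in each component's signal
    # genes, background terms uniform over the genome
    n_planted_per_comp <- min(2L, cfg$n_terms %/% 2L)
    annotation <- list()
    planted <- character(0)
    t_i <- 0L
    for (c_i in 1:2) {
      for (j in seq_len(n_planted_per_comp)) {
        t_i <- t_i + 1L
        nm <- sprintf("TERM%03d_planted_c%d", t_i, c_i)
        take <- min(cfg$term_size, K)
        members <- genes[sample(sig_idx[, c_i], take)]
        if (take < cfg$term_size)
          members <- c(members, sample(setdiff(genes, members),
                                       cfg$term_size - take))
        annotation[[nm]] <- members
        planted <- c(planted, nm)
      }
    }
    while (t_i < cfg$n_terms) {
      t_i <- t_i + 1L
      annotation[[sprintf("TERM%03d_background", t_i)]] <-
        sample(genes, cfg$term_size)
    }
    gene_sets <- list(
      signal_component1 = genes[sig_idx[, 1]],
      signal_component2 = genes[sig_idx[, 2]]
    )
    truth$gene_weights <- gene_weights
    truth$planted_term_ids <- planted
    list(expression = expr, truth = truth, annotation = annotation,
         gene_sets = gene_sets)
  })
}

#' Generate a planted-partition (stochastic block model) binary graph
#'
#' Convenience generator for community-detection benchmarks: `n_per_module`
#' nodes per module, edge probability `p_in` within and `p_out` between
#' modules. The largest connected component convention is not applied; with
#' the default probabilities the graph is connected with overwhelming
#' probability.
#'
#' @param n_modules,n_per_module partition shape.
#' @param p_in,p_out within/between edge probabilities.
#' @param seed RNG seed.
#' @return list with `graph` (a `binary_graph` without coordinates) and
#'   `labels` (planted module label per node).
#' @export
planted_partition_graph <- function(n_modules = 8L, n_per_module = 25L,
                                    p_in = 0.8, p_out = 0.02, seed = 1L) {
  n <- n_modules * n_per_module
  labels <- rep(seq_len(n_modules), each = n_per_module)
  with_seed(seed, {
    A <- matrix(0L, n, n)
    pm <- ifelse(outer(labels, labels, "=="), p_in, p_out)
    up <- upper.tri(A)
    A[up] <- as.integer(runif(sum(up)) < pm[up])
    A <- A + t(A)
  })
  ids <- region_ids_for(n)
  dimnames(A) <- list(ids, ids)
  g <- binary_graph_from_adjacency(A, coords = NULL)
  list(graph = g, labels = labels)
}

#' Generate a complete synthetic study with recoverable ground truth
#'
#' Runs the generator end-to-end: regions, time series, wavelet
#' connectivity, group-mean graph at the requested density, consensus
#' modular partition, subject-level nodal metrics (scored against the group
#' partition and averaged), and a planted expression matrix with GMT
#' annotations. This is the fixture factory used throughout the tests and
#' the acceptance analyses.
#'
#' @param cfg a [synthetic_config()].
#' @param density connection density of the analysis graph.
#' @param gamma Louvain resolution parameter.
#' @param n_runs Louvain runs entering the consensus partition.
#' @param scales wavelet scales pooled for the correlation matrix.
#' @return A list with all intermediate objects (`regions`, `truth`, `ts`,
#'   `conn`, `group_conn`, `graph`, `partition`, `metrics`, `expression`,
#'   `annotation`, `gene_sets`, `cfg`).
#' @export
synth_dataset <- function(cfg = synthetic_config(), density = 0.10,
                          gamma = 2, n_runs = 100L, scales = c(2L, 3L)) {
  rg <- generate_regions(cfg)
  ts <- generate_time_series(rg$regions, rg$truth, cfg)
  conn <- wavelet_correlation(ts, scales = scales)
  gm <- group_mean_matrix(conn)
  coords <- as.matrix(rg$regions[, c("x", "y", "z")])
  graph <- build_graph(gm, density = density, coords = coords)
  part <- consensus_partition(graph, gamma = gamma, n_runs = n_runs,
                              seed = derive_seed(cfg$seed, 4L))
  subject_graphs <- lapply(conn, build_graph, density = density,
                           coords = coords)
  ms <- nodal_metrics_set(subject_graphs, part, coords = coords)
  ex <- generate_expression(rg$regions, ms$mean, cfg, truth = rg$truth)
  list(regions = rg$regions, truth = ex$truth, ts = ts, conn = conn,
       group_conn = gm, graph = graph, partition = part, metrics = ms,
       expression = ex$expression, annotation = ex$annotation,
       gene_sets = ex$gene_sets, cfg = cfg)
}
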