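relabel_first_appearance <- function(labels) {
  match(labels, unique(labels))
}

#' Louvain community detection at resolution gamma
#'
#' One randomized run of the Louvain algorithm maximizing the
#' resolution-parameterized modularity
#' `Q(gamma) = sum_ij [A_ij - gamma k_i k_j / 2m] delta(c_i, c_j) / 2m`.
#' The node sweep order is randomized from the seed (runs with different
#' seeds can return different local optima, which the consensus procedure
#' exploits); given a seed the result is deterministic.
#'
#' @param graph a `binary_graph`.
#' @param gamma resolution parameter (> 0); larger values yield finer
#'   partitions.
#' @param seed RNG seed for the node sweep order.
#' @return A `modular_partition`: list with `labels` (module id per region,
#'   1..M in order of first appearance), `gamma`, `n_modules`,
#'   `modularity`.
#' @export
louvain_partition <- function(graph, gamma = 1, seed = 1L) {
  stopifnot(gamma > 0)
  g <- as_igraph(graph)
  n <- graph$n_regions
  with_seed(seed, {
    perm <- sample(n)
    gp <- igraph::permute(g, perm)
    memb_p <- igraph::membership(igraph::cluster_louvain(gp, resolution = gamma))
  })
  labels <- relabel_first_appearance(as.integer(memb_p[perm]))
  q <- igraph::modularity(g, labels, resolution = gamma)
  structure(list(labels = labels, gamma = gamma,
                 n_modules = max(labels), modularity = q,
                 region_ids = graph$region_ids),
            class = "modular_partition")
}

#' Consensus modular partition over repeated Louvain runs
#'
#' Lancichinetti-Fortunato consensus clustering: `n_runs` Louvain runs with
#' distinct seed-derived sweep orders are summarized in a co-classification
#' matrix (fraction of runs in which each pair of regions shares a module);
#' entries below `tau` are zeroed and the thresholded matrix is re-clustered
#' (as a weighted graph, at resolution 1) by the same number of runs,
#' iterating until all runs agree.
#'
#' @param graph a `binary_graph`.
#' @param gamma resolution parameter for the runs on the original graph.
#' @param n_runs number of Louvain runs per iteration.
#' @param seed master seed; run seeds are derived from it.
#' @param tau co-classification threshold (default 0.5).
#' @param max_iter maximum consensus iterations before failing.
#' @return A `modular_partition` with the consensus `labels`, `n_modules`,
#'   `modularity` (of the consensus labels on the original graph, at
#'   `gamma`), and `co_classification` (the first-level consensus
#'   frequency matrix).
#' @export
consensus_partition <- function(graph, gamma = 1, n_runs = 100L, seed = 1L,
                                tau = 0.5, max_iter = 20L) {
  stopifnot(n_runs >= 1L, gamma > 0)
  n <- graph$n_regions
  run_labels <- function(gobj, resolution, base_seed) {
    vapply(seq_len(n_runs), function(r) {
      with_seed(derive_seed(base_seed, r), {
        perm <- sample(n)
        gp <- igraph::permute(gobj, perm)
        memb <- igraph::membership(
          igraph::cluster_louvain(gp, resolution = resolution))
        relabel_first_appearance(as.integer(memb[perm]))
      })
    }, integer(n))
  }
  coclass <- function(L) {
    D <- matrix(0, n, n)
    for (r in seq_len(ncol(L))) D <- D + outer(L[, r], L[, r], "==")
    D / ncol(L)
  }
  g0 <- as_igraph(graph)
  L <- run_labels(g0, gamma, seed)
  D1 <- coclass(L)
  D <- D1
  labels <- L[, 1]
  converged <- all(D %in% c(0, 1))
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    Dt <- D
    Dt[Dt < tau] <- 0
    diag(Dt) <- 0
    gw <- igraph::graph_from_adjacency_matrix(Dt, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    L <- vapply(seq_len(n_runs), function(r) {
      with_seed(derive_seed(seed, 1000L * iter + r), {
        perm <- sample(n)
        gp <- igraph::permute(gw, perm)
        memb <- igraph::membership(igraph::cluster_louvain(gp, resolution = 1))
        relabel_first_appearance(as.integer(memb[perm]))
      })
    }, integer(n))
    D <- coclass(L)
    labels <- L[, 1]
    converged <- all(D %in% c(0, 1))
  }
  if (!converged) {
    cond <- simpleError("consensus partition did not converge")
    cond$co_classification <- D
    stop(cond)
  }
  q <- igraph::modularity(g0, labels, resolution = gamma)
  structure(list(labels = relabel_first_appearance(labels), gamma = gamma,
                 n_modules = length(unique(labels)), modularity = q,
                 co_classification = D1, region_ids = graph$region_ids),
            class = "modular_partition")
}

#' @export
print.modular_partition <- function(x, ...) {
  cat(sprintf("modular_partition: %d modules at gamma = %g (Q = %.4f)\n",
              x$n_modules, x$gamma, x$modularity))
  invisible(x)
}

#' Nodal topology and distance metrics
#'
#' For every region: total degree `k`, intra-modular degree `k_intra`
#' (edges to nodes in the same module), inter-modular degree `k_inter`,
#' participation coefficient `PC(i) = 1 - sum_m (k_i(m)/k_i)^2`, and mean
#' Euclidean connection distance `d` (mm) over the node's edges. Isolated
#' nodes get `NA` for PC and d and are reported in the `isolated`
#' attribute.
#'
#' @param graph a `binary_graph`.
#' @param partition a `modular_partition` whose labels cover all regions;
#'   typically the group consensus partition, so subject-level graphs are
#'   scored against the group's prototypical modular structure.
#' @param coords optional n x 3 centroid matrix; defaults to the graph's
#'   stored coordinates. Without coordinates `d` is `NA`.
#' @return A `nodal_metrics` data.frame: region_id, k, k_intra, k_inter,
#'   pc, d.
#' @export
nodal_metrics <- function(graph, partition, coords = NULL) {
  A <- graph$adjacency
  n <- graph$n_regions
  labels <- partition$labels
  if (length(labels) != n) stop("partition labels do not cover all regions")
  M <- max(labels)
  Mm <- outer(labels, seq_len(M), "==") * 1
  Kim <- A %*% Mm                       # k_i(m)
  k <- rowSums(A)
  k_intra <- Kim[cbind(seq_len(n), labels)]
  k_inter <- k - k_intra
  pc <- ifelse(k > 0, 1 - rowSums((Kim / pmax(k, 1))^2), NA_real_)
  coords <- coords %||% graph$coords
  d <- rep(NA_real_, n)
  if (!is.null(coords)) {
    e <- graph$edges
    len <- e$length_mm
    if (all(is.na(len)))
      len <- sqrt(rowSums((coords[e$i, , drop = FALSE] -
                           coords[e$j, , drop = FALSE])^2))
    sums <- rep(0, n); cnts <- rep(0, n)
    for (col in c("i", "j")) {
      t1 <- tapply(len, e[[col]], sum)
      ix <- as.integer(names(t1))
      sums[ix] <- sums[ix] + t1
      t2 <- tapply(len, e[[col]], length)
      cnts[ix] <- cnts[ix] + t2
    }
    d <- ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_)
  }
  out <- data.frame(region_id = graph$region_ids, k = k, k_intra = k_intra,
                    k_inter = k_inter, pc = pc, d = d,
                    stringsAsFactors = FALSE)
  attr(out, "isolated") <- graph$region_ids[k == 0]
  class(out) <- c("nodal_metrics", "data.frame")
  out
}

#' Subject-level nodal metrics aggregated against a group partition
#'
#' @param graphs list of `binary_graph` objects (one per subject).
#' @param partition the group `modular_partition` each subject is scored
#'   against.
#' @param coords region centroid matrix.
#' @param aggregate `"mean"` (default) or `"median"` across subjects.
#' @return list with `per_subject` (list of `nodal_metrics`), `mean` (the
#'   aggregated `nodal_metrics` data.frame) and `C` (the regions x 3
#'   response matrix of aggregated k_intra, k_inter, d).
#' @export
nodal_metrics_set <- function(graphs, partition, coords,
                              aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  per <- lapply(graphs, nodal_metrics, partition = partition, coords = coords)
  cols <- c("k", "k_intra", "k_inter", "pc", "d")
  arr <- vapply(per, function(m) as.matrix(m[, cols]),
                matrix(0, nrow(per[[1]]), length(cols)))
  agg <- apply(arr, c(1, 2), if (aggregate == "mean") mean else median,
               na.rm = TRUE)
  mean_df <- data.frame(region_id = per[[1]]$region_id, agg,
                        stringsAsFactors = FALSE)
  names(mean_df) <- c("region_id", cols)
  class(mean_df) <- c("nodal_metrics", "data.frame")
  C <- as.matrix(mean_df[, c("k_intra", "k_inter", "d")])
  rownames(C) <- mean_df$region_id
  list(per_subject = per, mean = mean_df, C = C)
}

# Degree-preserving rewiring that keeps the graph connected
# (bounded retries; returns the last attempt if none is connected).
rewire_connected <- function(g, swaps_per_edge = 10, max_tries = 20L) {
  niter <- swaps_per_edge * igraph::ecount(g)
  for (t in seq_len(max_tries)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
    if (igraph::is_connected(gr)) return(gr)
  }
  gr
}

rich_club_phi <- function(deg, A) {
  ks <- sort(unique(deg))
  ks <- ks[ks < max(deg)]
  phi <- vapply(ks, function(k) {
    keep <- which(deg > k)
    nk <- length(keep)
    if (nk < 2) return(NA_real_)
    sum(A[keep, keep]) / (nk * (nk - 1))
  }, numeric(1))
  data.frame(k = ks, phi = phi)
}

#' Global network statistics with degree-preserving null comparison
#'
#' Mean local clustering coefficient `C` (isolates counted as 0),
#' characteristic path length `L` (mean shortest path in hops),
#' small-worldness `sigma = (C/C_rand) / (L/L_rand)`, and the normalized
#' rich-club curve `phi(k)/mean phi_rand(k)`, where the null statistics are
#' means over `n_null` degree-preserving rewirings (double edge swaps,
#' `swaps_per_edge * |E|` attempted swaps each, rewired graphs re-drawn if
#' disconnected).
#'
#' @param graph a `binary_graph` (connected).
#' @param partition optional `modular_partition`; if given, its modularity
#'   is reported as `Q`.
#' @param n_null number of rewired null graphs.
#' @param seed RNG seed.
#' @param swaps_per_edge attempted swaps per edge in each rewiring.
#' @return A `global_metrics` list: `Q`, `C`, `L`, `sigma`, `C_rand`,
#'   `L_rand`, `rich_club` (data.frame k, phi, phi_rand, phi_norm).
#' @export
global_metrics <- function(graph, partition = NULL, n_null = 100L, seed = 1L,
                           swaps_per_edge = 10) {
  g <- as_igraph(graph)
  if (!igraph::is_connected(g)) stop("graph must be connected")
  Cc <- mean(igraph::transitivity(g, type = "localundirected",
                                  isolates = "zero"))
  Ll <- igraph::mean_distance(g, directed = FALSE)
  deg <- igraph::degree(g)
  rc <- rich_club_phi(deg, graph$adjacency)
  null_stats <- with_seed(seed, {
    lapply(seq_len(n_null), function(i) {
      gr <- rewire_connected(g, swaps_per_edge = swaps_per_edge)
      Ar <- igraph::as_adjacency_matrix(gr, sparse = FALSE)
      list(C = mean(igraph::transitivity(gr, type = "localundirected",
                                         isolates = "zero")),
           L = igraph::mean_distance(gr, directed = FALSE),
           phi = rich_club_phi(igraph::degree(gr), Ar)$phi)
    })
  })
  C_rand <- mean(vapply(null_stats, `[[`, numeric(1), "C"))
  L_rand <- mean(vapply(null_stats, `[[`, numeric(1), "L"))
  phi_rand <- rowMeans(vapply(null_stats, `[[`, numeric(nrow(rc)), "phi"),
                       na.rm = TRUE)
  rc$phi_rand <- phi_rand
  rc$phi_norm <- rc$phi / phi_rand
  structure(list(
    Q = if (!is.null(partition)) partition$modularity else NA_real_,
    C = Cc, L = Ll, sigma = (Cc / C_rand) / (Ll / L_rand),
    C_rand = C_rand, L_rand = L_rand, rich_club = rc
  ), class = "global_metrics")
}

#' One-way ANOVA of a nodal metric across region classes
#'
#' @param values numeric metric per region.
#' @param classes class label per region (factor or vector); at least two
#'   classes, each with at least two regions.
#' @return Named list: `F`, `df1` (`n_classes - 1`), `df2`
#'   (`n - n_classes`), `p`.
#' @export
class_anova <- function(values, classes) {
  ok <- stats::complete.cases(values, classes)
  values <- values[ok]; classes <- factor(classes[ok])
  tab <- table(classes)
  if (length(tab) < 2L) stop("class_anova requires at least two classes")
  if (any(tab < 2L)) stop("every class needs at least two regions")
  fit <- anova(lm(values ~ classes))
  list(F = fit[["F value"]][1], df1 = fit[["Df"]][1], df2 = fit[["Df"]][2],
       p = fit[["Pr(>F)"]][1])
}
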