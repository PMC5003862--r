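# round half away from zero (fixed edge-count convention)
round_half_up <- function(x) floor(x + 0.5)

binary_graph_from_adjacency <- function(A, coords = NULL, density = NA,
                                        warn = NULL) {
  n <- nrow(A)
  ids <- rownames(A) %||% region_ids_for(n)
  ut <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  len <- if (!is.null(coords)) {
    sqrt(rowSums((coords[ut[, 1], , drop = FALSE] -
                  coords[ut[, 2], , drop = FALSE])^2))
  } else rep(NA_real_, nrow(ut))
  edges <- data.frame(
    i = ut[, 1], j = ut[, 2],
    region_i = ids[ut[, 1]], region_j = ids[ut[, 2]],
    r = NA_real_, length_mm = len, stringsAsFactors = FALSE
  )
  structure(
    list(adjacency = A, edges = edges, n_regions = n, region_ids = ids,
         coords = coords, density = nrow(edges) / (n * (n - 1) / 2),
         density_target = density, warnings = warn),
    class = "binary_graph"
  )
}

#' Build an MST-anchored binary graph at a target connection density
#'
#' The minimum spanning tree of the dissimilarity `1 - r` guarantees a
#' single connected component at any density; remaining node pairs are then
#' superimposed in order of decreasing correlation `r` (signed, so negative
#' correlations are only ever added after all positive ones), with ties
#' broken by lexicographic region order, until the target edge count
#' `max(n - 1, round(density * n(n-1)/2))` is reached.
#'
#' @param mat a `connectivity_matrix` or plain symmetric correlation matrix.
#' @param density target fraction of possible edges (0-1).
#' @param coords optional n x 3 matrix of region centroids (mm) used to
#'   attach a Euclidean length to every edge.
#' @return A `binary_graph`: symmetric zero-diagonal adjacency, edge table
#'   (i, j, region ids, r, length_mm), achieved density. If the requested
#'   density implies fewer edges than the spanning tree, the MST is
#'   returned and a warning is recorded in `$warnings`.
#' @export
build_graph <- function(mat, density = 0.10, coords = NULL) {
  r <- if (inherits(mat, "connectivity_matrix")) mat$r else mat
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (density < 0 || density > 1) stop("density must be in [0, 1]")
  n <- nrow(r)
  ids <- rownames(r) %||% region_ids_for(n)
  m_target <- max(n - 1L, round_half_up(density * n * (n - 1) / 2))
  warn <- NULL
  if (round_half_up(density * n * (n - 1) / 2) < n - 1L)
    warn <- sprintf(
      "density %.4f implies fewer than n-1 edges; returning the MST", density)
  g_full <- igraph::graph_from_adjacency_matrix(
    1 - r, mode = "undirected", weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g_full, algorithm = "prim")
  mst_el <- igraph::as_edgelist(mst, names = FALSE)
  mst_el <- cbind(pmin(mst_el[, 1], mst_el[, 2]),
                  pmax(mst_el[, 1], mst_el[, 2]))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[ut]
  in_mst <- logical(nrow(ut))
  key <- ut[, 1] * (n + 1) + ut[, 2]
  in_mst[match(mst_el[, 1] * (n + 1) + mst_el[, 2], key)] <- TRUE
  ord <- order(-rv, ut[, 1], ut[, 2])
  extra_needed <- m_target - sum(in_mst)
  chosen <- in_mst
  if (extra_needed > 0L) {
    cand <- ord[!in_mst[ord]]
    chosen[cand[seq_len(extra_needed)]] <- TRUE
  }
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  sel <- ut[chosen, , drop = FALSE]
  A[sel] <- 1L
  A[sel[, c(2, 1), drop = FALSE]] <- 1L
  g <- binary_graph_from_adjacency(A, coords = coords, density = density,
                                   warn = warn)
  g$edges$r <- r[cbind(g$edges$i, g$edges$j)]
  g
}

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected",
                                      diag = FALSE)
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf(
    "binary_graph: %d regions, %d edges (density %.3f, target %.3f)\n",
    x$n_regions, nrow(x$edges), x$density,
    ifelse(is.na(x$density_target), x$density, x$density_target)))
  if (!is.null(x$warnings)) cat("warning:", x$warnings, "\n")
  invisible(x)
}
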