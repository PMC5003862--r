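#' Collapse probe-level expression to gene level
#'
#' Probes without a gene symbol are dropped (their count is recorded in the
#' `n_unmapped` attribute); probes mapping to the same gene are averaged.
#'
#' @param expr probe x sample numeric matrix (rownames = probe ids).
#' @param probe_map data.frame with columns `probe_id`, `gene_symbol`
#'   (`NA` or `""` marks an unmapped probe).
#' @return gene x sample matrix with attribute `n_unmapped`.
#' @export
collapse_probes <- function(expr, probe_map) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  sym <- probe_map$gene_symbol[match(rownames(expr), probe_map$probe_id)]
  sym[sym == ""] <- NA
  mapped <- !is.na(sym)
  n_unmapped <- sum(!mapped)
  if (!any(mapped)) stop("no probes mapped to gene symbols")
  sub <- expr[mapped, , drop = FALSE]
  g <- factor(sym[mapped])
  out <- rowsum(sub, g) / as.vector(table(g))
  out <- as.matrix(out)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Match regions to their nearest expression samples
#'
#' Each region centroid receives, per donor, the expression of the nearest
#' sample under Euclidean distance, considering both the centroid and its
#' left-right mirror (x-coordinate sign flip) so that homologous regions in
#' both hemispheres are pooled; the selected profiles are then averaged
#' across donors and hemispheres. Ties are broken by the lower sample index
#' (input order).
#'
#' @param regions region table with columns x, y, z (and region_id).
#' @param expr gene x sample matrix.
#' @param sample_coords data.frame with columns x, y, z and optionally
#'   `donor` (one row per column of `expr`).
#' @param max_distance_mm regions with no sample within this distance (in
#'   either hemisphere) are flagged unmatched and filled with `NA`.
#' @param mirror set `FALSE` to disable hemispheric mirroring.
#' @return gene x region matrix with attribute `unmatched` (region ids).
#' @export
match_regions <- function(regions, expr, sample_coords,
                          max_distance_mm = Inf, mirror = TRUE) {
  stopifnot(ncol(expr) == nrow(sample_coords))
  donors <- sample_coords$donor %||% rep("donor1", nrow(sample_coords))
  sc <- as.matrix(sample_coords[, c("x", "y", "z")])
  ctr <- as.matrix(regions[, c("x", "y", "z")])
  out <- matrix(NA_real_, nrow(expr), nrow(regions),
                dimnames = list(rownames(expr), regions$region_id))
  unmatched <- character(0)
  udon <- unique(donors)
  for (ri in seq_len(nrow(regions))) {
    targets <- ctr[ri, , drop = FALSE]
    if (mirror) targets <- rbind(targets, targets * c(-1, 1, 1))
    picks <- integer(0)
    for (dn in udon) {
      sidx <- which(donors == dn)
      for (ti in seq_len(nrow(targets))) {
        dd <- sqrt(colSums((t(sc[sidx, , drop = FALSE]) - targets[ti, ])^2))
        best <- sidx[which.min(dd)]           # which.min takes the first tie
        if (min(dd) <= max_distance_mm) picks <- c(picks, best)
      }
    }
    if (length(picks) == 0L) {
      unmatched <- c(unmatched, regions$region_id[ri])
    } else {
      out[, ri] <- rowMeans(expr[, picks, drop = FALSE])
    }
  }
  attr(out, "unmatched") <- unmatched
  out
}

#' Z-score each gene's expression across regions
#'
#' Per-gene standardization (sample standard deviation); genes with zero
#' variance are dropped and counted in the `dropped_genes` attribute.
#'
#' @param T_raw gene x region numeric matrix.
#' @return gene x region matrix with every row mean 0 and s.d. 1.
#' @export
zscore_expression <- function(T_raw) {
  stopifnot(is.matrix(T_raw), ncol(T_raw) >= 2)
  mu <- rowMeans(T_raw)
  s <- apply(T_raw, 1, sd)
  keep <- s > 0
  out <- (T_raw[keep, , drop = FALSE] - mu[keep]) / s[keep]
  attr(out, "dropped_genes") <- rownames(T_raw)[!keep]
  out
}

#' Flag and remove regions with outlying expression profiles
#'
#' A region is an outlier when its mean correlation to all other regions'
#' expression profiles falls below `median - threshold * IQR` of those mean
#' correlations across regions. Remaining regions are re-Z-scored. If more
#' than 20% of regions are flagged the call errors, since that suggests an
#' upstream region/sample mismatch rather than a few bad profiles.
#'
#' @param T gene x region Z-scored matrix.
#' @param threshold IQR multiplier (default 3; `Inf` disables exclusion).
#' @return list with `expression` (re-Z-scored matrix) and `excluded`
#'   (region ids).
#' @export
exclude_outlier_regions <- function(T, threshold = 3) {
  n <- ncol(T)
  rc <- cor(T)
  mean_cor <- (rowSums(rc) - 1) / (n - 1)
  cut <- median(mean_cor) - threshold * IQR(mean_cor)
  bad <- if (is.finite(cut)) which(mean_cor < cut) else integer(0)
  if (length(bad) > 0.2 * n)
    stop("more than 20% of regions flagged as expression outliers; ",
         "check region/sample matching")
  excluded <- colnames(T)[bad]
  keep <- T[, setdiff(seq_len(n), bad), drop = FALSE]
  list(expression = zscore_expression(keep), excluded = excluded)
}

#' Assemble a Z-scored gene x region expression matrix
#'
#' Fixed pipeline order: probe collapse, nearest-sample region matching
#' (donor- and hemisphere-averaged), Z-scoring, outlier-region exclusion,
#' re-Z-scoring. Dimensions in and out of each step are recorded in the
#' `log` element.
#'
#' @param regions region table.
#' @param probe_expr probe x sample matrix.
#' @param probe_map probe-to-gene map (see [collapse_probes()]).
#' @param sample_coords sample coordinate table (see [match_regions()]).
#' @param max_distance_mm see [match_regions()].
#' @param outlier_threshold see [exclude_outlier_regions()].
#' @return list with `expression` (genes x retained regions),
#'   `excluded_regions`, `log` (character vector of step records).
#' @export
assemble_expression <- function(regions, probe_expr, probe_map,
                                sample_coords, max_distance_mm = Inf,
                                outlier_threshold = 3) {
  log <- character(0)
  step <- function(msg) log <<- c(log, msg)
  ge <- collapse_probes(probe_expr, probe_map)
  step(sprintf("collapse_probes: %d probes -> %d genes (%d unmapped dropped)",
               nrow(probe_expr), nrow(ge), attr(ge, "n_unmapped")))
  mt <- match_regions(regions, ge, sample_coords,
                      max_distance_mm = max_distance_mm)
  unmatched <- attr(mt, "unmatched")
  if (length(unmatched) > 0) {
    mt <- mt[, !(colnames(mt) %in% unmatched), drop = FALSE]
    step(sprintf("match_regions: %d regions unmatched (%s)",
                 length(unmatched), paste(unmatched, collapse = ", ")))
  }
  step(sprintf("match_regions: %d genes x %d regions", nrow(mt), ncol(mt)))
  tz <- zscore_expression(mt)
  step(sprintf("zscore: dropped %d zero-variance genes",
               length(attr(tz, "dropped_genes"))))
  ex <- exclude_outlier_regions(tz, threshold = outlier_threshold)
  step(sprintf("exclude_outlier_regions: excluded %d regions",
               length(ex$excluded)))
  list(expression = ex$expression, excluded_regions = ex$excluded, log = log)
}
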