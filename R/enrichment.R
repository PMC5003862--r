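#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for the number of annotated genes among the top `n` of a
#' ranked list of `N` genes containing `K` annotated genes, evaluated in
#' log space for numerical stability.
#'
#' @param N total genes. @param K annotated genes. @param n cutoff size.
#' @param k observed overlap.
#' @return the tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || k > min(K, n) || K > N || n > N)
    stop("inconsistent hypergeometric counts")
  if (k == 0) return(1)
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

# Minimum hypergeometric statistic of a 0/1 membership vector ordered by
# rank: the smallest tail over cutoffs ending at a hit.
mhg_statistic <- function(member) {
  N <- length(member)
  K <- sum(member)
  if (K == 0L) return(list(mhg = 1, cutoff = 0L))
  hits <- which(member == 1L)
  k_at <- seq_along(hits)
  tails <- phyper(k_at - 1, K, N - K, hits, lower.tail = FALSE, log.p = TRUE)
  best <- which.min(tails)
  list(mhg = exp(tails[best]), cutoff = hits[best])
}

# Exact p-value of the mHG statistic by dynamic programming over the
# hypergeometric path lattice: the probability that a uniformly random
# arrangement of K hits among N genes attains min-tail <= s anywhere.
mhg_exact_pvalue <- function(s, N, K) {
  if (K == 0L) return(1)
  # P[n, k]: probability mass of paths reaching (n genes seen, k hits)
  # without having entered the rejection region {HGT(N,K,n,k) <= s}.
  prev <- c(1, rep(0, K))      # n = 0
  s_log <- log(s) + 1e-12      # tolerate FP noise at the boundary
  for (n in seq_len(N)) {
    k_max <- min(n, K)
    k_min <- max(0L, n - (N - K))
    ks <- k_min:k_max
    tails <- phyper(ks - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
    cur <- rep(0, K + 1)
    # transition: hit with prob (K - k)/(N - n + 1), miss otherwise
    k_all <- 0:K
    p_hit <- pmax(0, (K - k_all) / (N - n + 1))
    cur <- prev * (1 - p_hit)                     # miss: k stays
    cur[-1] <- cur[-1] + (prev * p_hit)[-(K + 1)] # hit: k + 1
    bar <- ks[tails <= s_log]
    cur[bar + 1] <- 0
    prev <- cur
  }
  max(0, min(1, 1 - sum(prev)))
}

#' Ranked-gene-list enrichment by the minimum hypergeometric statistic
#'
#' Threshold-free enrichment of GMT terms in a ranked gene list: for each
#' term the hypergeometric tail is minimized over all rank cutoffs (mHG).
#' Both list ends are tested (most positively weighted genes via the given
#' ranking, most negatively weighted via its reversal). The term-level
#' p-value is the exact mHG p (dynamic programming) when the list has at
#' most `exact_limit` genes, otherwise a Bonferroni bound over the distinct
#' cutoffs actually attainable (one per annotated gene). BH-FDR is applied
#' across all term-by-direction rows. Terms annotated with more than 2500
#' genes or with `P_FDR >= 0.001` are flagged, not removed.
#'
#' @param ranking a `gene_ranking` (or data.frame with columns `gene`,
#'   `z`); order of decreasing Z defines the positive end.
#' @param annotation named list of gene-symbol vectors (see [read_gmt()]).
#' @param exact_limit largest list size for the exact p-value.
#' @param fdr_threshold FDR flag threshold (default 0.001).
#' @param max_term_size size flag threshold (default 2500).
#' @return An `enrichment_table` data.frame: term, direction (`pos`/`neg`),
#'   n_annotated, mhg, cutoff, p, p_fdr, overlap_genes, flag_large_term,
#'   flag_fdr. Attribute `n_dropped_genes` counts annotation genes absent
#'   from the ranking.
#' @export
ranked_enrichment <- function(ranking, annotation, exact_limit = 5000L,
                              fdr_threshold = 0.001, max_term_size = 2500L) {
  if (length(annotation) == 0L) stop("empty annotation")
  genes_ranked <- ranking$gene[order(ranking$z, decreasing = TRUE)]
  N <- length(genes_ranked)
  dropped <- sum(!(unique(unlist(annotation)) %in% genes_ranked))
  ends <- list(pos = genes_ranked, neg = rev(genes_ranked))
  rows <- list()
  for (dir_name in names(ends)) {
    glist <- ends[[dir_name]]
    for (term in names(annotation)) {
      tg <- unique(annotation[[term]])
      member <- as.integer(glist %in% tg)
      K <- sum(member)
      st <- mhg_statistic(member)
      p <- if (K == 0L) 1
           else if (N <= exact_limit) mhg_exact_pvalue(st$mhg, N, K)
           else min(1, K * st$mhg)
      overlap <- if (st$cutoff > 0) glist[seq_len(st$cutoff)][
        member[seq_len(st$cutoff)] == 1L] else character(0)
      rows[[length(rows) + 1L]] <- data.frame(
        term = term, direction = dir_name, n_annotated = K,
        mhg = st$mhg, cutoff = st$cutoff, p = p,
        overlap_genes = paste(overlap, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p, method = "BH")
  out$flag_large_term <- out$n_annotated > max_term_size
  out$flag_fdr <- out$p_fdr >= fdr_threshold
  out <- out[, c("term", "direction", "n_annotated", "mhg", "cutoff", "p",
                 "p_fdr", "overlap_genes", "flag_large_term", "flag_fdr")]
  out <- out[order(out$p_fdr, out$p), ]
  rownames(out) <- NULL
  attr(out, "n_dropped_genes") <- dropped
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Permutation test of a candidate gene set against a ranking
#'
#' The observed statistic is the mean bootstrap Z of the candidate genes;
#' the null distribution is the mean Z of `n_perm` uniformly drawn gene
#' sets of the same size. One-sided (enrichment among positive weights),
#' add-one p-value. Candidate genes absent from the ranking are dropped
#' and the null draw size matches the retained count.
#'
#' @param ranking a `gene_ranking` (columns `gene`, `z`).
#' @param gene_set character vector of candidate gene symbols.
#' @param n_perm number of random draws.
#' @param seed RNG seed.
#' @return A `perm_test` list with `observed`, `null`, `p`,
#'   `n_retained`, `n_dropped`.
#' @export
candidate_set_test <- function(ranking, gene_set, n_perm = 1000L, seed = 1L) {
  gene_set <- unique(gene_set)
  keep <- gene_set %in% ranking$gene
  retained <- gene_set[keep]
  if (length(retained) == 0L) stop("no candidate genes present in the ranking")
  z <- ranking$z[match(retained, ranking$gene)]
  observed <- mean(z)
  m <- length(retained)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(b) mean(ranking$z[sample(nrow(ranking), m)]),
           numeric(1))
  })
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null = null, p = p, scheme = "uniform",
                 n_perm = n_perm, seed = seed, n_retained = m,
                 n_dropped = sum(!keep)),
            class = "perm_test")
}
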