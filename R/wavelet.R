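# Daubechies-4 (extremal phase, 4 taps) scaling filter, unit L2 norm.
db4_scaling <- function() {
  s3 <- sqrt(3)
  c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
}

# Quadrature mirror wavelet filter: h_l = (-1)^l g_{L-1-l}.
db4_wavelet <- function() {
  g <- db4_scaling()
  L <- length(g)
  rev(g) * (-1)^(seq_len(L) - 1)
}

#' Maximal-overlap discrete wavelet transform (Daubechies-4)
#'
#' Shift-invariant MODWT with the 4-tap Daubechies filter and a reflection
#' boundary: the series is extended to twice its length by reflection, the
#' circular MODWT is computed in the frequency domain, and the first
#' `length(x)` coefficients of each level are retained. Coefficients at
#' level j capture the dyadic frequency band given by [scale_band()].
#'
#' @param x numeric vector, or a matrix with one series per column.
#' @param levels integer vector of decomposition levels (scales) to return.
#' @return A list of matrices (one per level, named `d1`, `d2`, ...), each
#'   `length-of-series x n-series`.
#' @export
modwt <- function(x, levels = 1:3) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  T_len <- nrow(x)
  J <- max(levels)
  if (T_len < 2^(J + 2))
    stop("series too short for requested wavelet scale: need >= ", 2^(J + 2),
         " timepoints for scale ", J)
  xe <- rbind(x, x[rev(seq_len(T_len)), , drop = FALSE])
  N <- nrow(xe)
  g <- db4_scaling() / sqrt(2)       # MODWT filters
  h <- db4_wavelet() / sqrt(2)
  k <- 0:(N - 1)
  Gf <- colSums(g * exp(-2i * pi * outer(0:3, k) / N))
  Hf <- colSums(h * exp(-2i * pi * outer(0:3, k) / N))
  Xf <- mvfft(xe)
  out <- list()
  Gprod <- rep(1 + 0i, N)            # product of scaling transfers below level j
  for (j in seq_len(J)) {
    idx <- (2^(j - 1) * k) %% N + 1
    Hj <- Hf[idx] * Gprod
    if (j %in% levels) {
      Wj <- Re(mvfft(Hj * Xf, inverse = TRUE)) / N
      out[[paste0("d", j)]] <- Wj[seq_len(T_len), , drop = FALSE]
    }
    Gprod <- Gprod * Gf[idx]
  }
  out[paste0("d", sort(levels))]
}

#' Dyadic frequency band of a wavelet scale
#'
#' @param tr_seconds sampling interval in seconds.
#' @param scale wavelet scale (level), >= 1.
#' @return Named numeric vector `c(f_low, f_high)` in Hz:
#'   `1/(2^(scale+1) * TR)` to `1/(2^scale * TR)`.
#' @export
scale_band <- function(tr_seconds, scale) {
  stopifnot(tr_seconds > 0, scale >= 1)
  c(f_low = 1 / (2^(scale + 1) * tr_seconds),
    f_high = 1 / (2^scale * tr_seconds))
}

#' Wavelet correlation matrices from regional time series
#'
#' For each subject, regional time series are decomposed by the Daubechies-4
#' MODWT and the coefficients of the requested scales are pooled
#' (concatenated) before computing the Pearson correlation between every
#' pair of regions. Pooling scales 2 and 3 at TR = 2.42 s covers the
#' 0.026-0.103 Hz band conventionally used for resting-state fMRI.
#'
#' @param ts a `time_series_set` (see [generate_time_series()]), or a
#'   regions x timepoints matrix for a single subject.
#' @param scales integer vector of wavelet scales to pool.
#' @param tr_seconds sampling interval; taken from `ts` when available.
#' @return A list of `connectivity_matrix` objects (one per subject), each
#'   with elements `r` (symmetric correlation matrix, unit diagonal),
#'   `scales`, and `subject`.
#' @export
wavelet_correlation <- function(ts, scales = c(2L, 3L), tr_seconds = NULL) {
  if (length(scales) == 0L) stop("scales must be nonempty")
  if (is.matrix(ts)) {
    ts <- structure(
      list(values = array(ts, dim = c(1, nrow(ts), ncol(ts))),
           tr_seconds = tr_seconds %||% 1,
           region_ids = rownames(ts) %||% region_ids_for(nrow(ts))),
      class = "time_series_set")
  }
  vals <- ts$values
  n_sub <- dim(vals)[1]; n_reg <- dim(vals)[2]; T_len <- dim(vals)[3]
  if (T_len < 2^(max(scales) + 2))
    stop("timepoints must be >= 2^(max scale + 2) = ", 2^(max(scales) + 2))
  ids <- ts$region_ids %||% region_ids_for(n_reg)
  lapply(seq_len(n_sub), function(s) {
    X <- t(vals[s, , , drop = TRUE])           # timepoints x regions
    sds <- apply(X, 2, sd)
    if (any(sds == 0))
      stop("constant time series for region(s): ",
           paste(ids[sds == 0], collapse = ", "))
    w <- modwt(X, levels = scales)
    pooled <- do.call(rbind, w)
    r <- cor(pooled)
    r[r > 1] <- 1; r[r < -1] <- -1
    diag(r) <- 1
    r <- (r + t(r)) / 2
    dimnames(r) <- list(ids, ids)
    structure(list(r = r, scales = sort(scales), subject = s),
              class = "connectivity_matrix")
  })
}

#' Element-wise mean of connectivity matrices
#'
#' @param mats list of `connectivity_matrix` objects (or plain square
#'   matrices) sharing the same region set and scales.
#' @return A `connectivity_matrix` tagged `"group-mean"`, with the diagonal
#'   forced to 1.
#' @export
group_mean_matrix <- function(mats) {
  if (length(mats) == 0L) stop("empty list of connectivity matrices")
  rs <- lapply(mats, function(m) if (inherits(m, "connectivity_matrix")) m$r else m)
  d <- dim(rs[[1]])
  for (m in rs) if (!identical(dim(m), d))
    stop("connectivity matrices have mismatched dimensions")
  mean_r <- Reduce(`+`, rs) / length(rs)
  diag(mean_r) <- 1
  scales <- if (inherits(mats[[1]], "connectivity_matrix")) mats[[1]]$scales else NA
  structure(list(r = mean_r, scales = scales, subject = "group-mean"),
            class = "connectivity_matrix")
}
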