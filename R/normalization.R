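#' @title TMM between-library normalization
#' @name normalization
NULL

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Computes per-library scaling factors from trimmed, precision-weighted
#' means of per-position log2 count ratios (M-values) against a reference
#' library. The reference is the library whose 75th-percentile
#' library-size-normalized count is closest to the mean of those
#' quantiles. For each library, positions with zero counts in either the
#' library or the reference are excluded; the top and bottom `trim_m`
#' fraction of M-values and `trim_a` fraction of A-values (average log2
#' abundance) are trimmed; remaining M-values are averaged with inverse
#' delta-method variance weights. Factors are rescaled so their geometric
#' mean is 1.
#'
#' @param counts Non-negative count matrix, positions x libraries.
#' @param lib_sizes Library sizes (defaults to column sums).
#' @param trim_m Two-sided trim fraction on M-values (default 0.30).
#' @param trim_a Two-sided trim fraction on A-values (default 0.05).
#' @return Named numeric vector of scaling factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 libraries")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")

  q75 <- apply(counts, 2L, stats::quantile, probs = 0.75) / lib_sizes
  ref <- which.min(abs(q75 - mean(q75)))

  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib_sizes[j], lib_sizes[ref],
             trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# TMM factor of one library against the reference library.
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    warning("library has no positive overlap with the reference; factor 1")
    return(1)
  }
  obs <- obs[keep]; ref <- ref[keep]
  p_o <- obs / n_obs; p_r <- ref / n_ref
  m <- log2(p_o / p_r)
  a <- 0.5 * log2(p_o * p_r)
  # delta-method variance of M
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (length(m) == 0L || max(abs(m)) < 1e-6) return(1)

  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  f <- sum(m[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f)) return(1)
  2^f
}
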