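# Per-contig comparison of a forward/reverse library pair: two-proportion
# Z test on tag counts, Storey q-values for FDR control, and log2 fold
# change on RPKM.

#' Two-proportion Z test on tag counts
#'
#' Compares the per-library proportions of reads mapped to one contig,
#' `p_f = k_f/N_f` versus `p_r = k_r/N_r`, with the pooled-variance
#' standard-normal statistic
#' `z = (p_f - p_r) / sqrt(p0 (1 - p0) (1/N_f + 1/N_r))` where
#' `p0 = (k_f + k_r)/(N_f + N_r)`, the classical test for comparing tag
#' counts between two sequenced libraries.  No continuity correction is
#' applied, so `z^2` equals the 2x2 chi-square statistic on the same table.
#' Degenerate tables (pooled proportion 0 or 1) give `z = 0`, `p = 1`.
#'
#' @param k_f,k_r mapped-read counts in the forward and reverse library
#'   (vectorised).
#' @param N_f,N_r library totals (>= 1).
#' @return data.frame with columns `z` and `p` (two-sided).
#' @export
#' @examples
#' proportion_test(30, 1000, 10, 1000)
proportion_test <- function(k_f, N_f, k_r, N_r) {
  if (any(N_f < 1) || any(N_r < 1)) stop_config("library totals must be >= 1")
  if (any(k_f < 0) || any(k_r < 0) || any(k_f > N_f) || any(k_r > N_r))
    stop_config("counts must satisfy 0 <= k <= N")
  p_f <- k_f / N_f
  p_r <- k_r / N_r
  p0 <- (k_f + k_r) / (N_f + N_r)
  v <- p0 * (1 - p0) * (1 / N_f + 1 / N_r)
  z <- ifelse(v > 0, (p_f - p_r) / sqrt(v), 0)
  data.frame(z = z, p = 2 * pnorm(-abs(z)))
}

#' Storey estimate of the null proportion pi0
#'
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` evaluated over a grid
#' of lambda values, smoothed with a cubic smoothing spline (3 degrees of
#' freedom) and read off at the largest lambda, then clamped to `(0, 1]`.
#' With a single lambda the raw estimate at that lambda is used.
#'
#' @param pvalues numeric vector of p-values.
#' @param lambda grid of tuning values in `(0, 1)`.
#' @return the pi0 estimate.
#' @export
estimate_pi0 <- function(pvalues, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(pvalues) == 0) stop_config("at least one p-value is required")
  if (any(lambda <= 0) || any(lambda >= 1))
    stop_config("lambda grid must lie in (0, 1)")
  m <- length(pvalues)
  lambda <- sort(unique(lambda))
  pi0_l <- vapply(lambda, function(l) sum(pvalues > l) / (m * (1 - l)), 0)
  est <- if (length(lambda) >= 4) {
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    predict(fit, x = max(lambda))$y
  } else {
    pi0_l[length(pi0_l)]
  }
  min(1, max(est, .Machine$double.eps))
}

#' Storey q-values
#'
#' `q(p_(i)) = min_{j >= i} pi0 m p_(j) / j` over the sorted p-values,
#' mapped back to input order and capped at 1.  With `pi0 = 1` this reduces
#' to Benjamini-Hochberg adjusted p-values.
#'
#' @param pvalues numeric p-values.
#' @param pi0 null proportion in `(0, 1]`; defaults to [estimate_pi0()] on
#'   `pvalues`.
#' @return numeric q-values in input order.
#' @export
qvalues <- function(pvalues, pi0 = NULL) {
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  if (is.null(pi0)) pi0 <- estimate_pi0(pvalues)
  if (pi0 <= 0 || pi0 > 1) stop_config("pi0 must be in (0, 1]")
  o <- order(pvalues)
  q_sorted <- pi0 * m * pvalues[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Log2 fold change on RPKM
#'
#' `log2(rpkm_f / rpkm_r)` when both sides are expressed; `+Inf` when only
#' the forward side is, `-Inf` when only the reverse side is, and `NA` when
#' neither is.
#'
#' @param rpkm_f,rpkm_r RPKM values (>= 0, vectorised).
#' @return numeric log2 fold changes.
#' @export
log2_fold_change <- function(rpkm_f, rpkm_r) {
  if (any(rpkm_f < 0) || any(rpkm_r < 0))
    stop_config("RPKM values must be >= 0")
  out <- rep(NA_real_, length(rpkm_f))
  both <- rpkm_f > 0 & rpkm_r > 0
  out[both] <- log2(rpkm_f[both] / rpkm_r[both])
  out[rpkm_f > 0 & rpkm_r == 0] <- Inf
  out[rpkm_f == 0 & rpkm_r > 0] <- -Inf
  out
}

#' Compare a forward/reverse library pair per contig
#'
#' Runs the two-proportion test on raw mapped-read counts (the test is
#' count-based; RPKM enters only through the fold change), estimates pi0
#' and q-values over the contigs with at least one read in the pair, and
#' computes the RPKM log2 fold change.  Contigs with no reads in either
#' library get `z = 0`, `p = 1`, `q = 1`.
#'
#' @param quant_f,quant_r `ssh_quant` objects for the forward and reverse
#'   library, quantified against the same reference.
#' @param q_cut significance cutoff on the q-value (inclusive).
#' @param pi0_lambda lambda grid (or single lambda) for [estimate_pi0()].
#' @return data.frame of class `ssh_diff`: `contig_id`, `k_f`, `k_r`,
#'   `N_f`, `N_r`, `rpkm_f`, `rpkm_r`, `z`, `p`, `q`, `log2fc`,
#'   `significant`.
#' @export
compare_libraries <- function(quant_f, quant_r, q_cut = 0.05,
                              pi0_lambda = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(identical(quant_f$counts$contig_id, quant_r$counts$contig_id))
  k_f <- quant_f$counts$read_count
  k_r <- quant_r$counts$read_count
  N_f <- max(quant_f$library_total_mapped, 1L)
  N_r <- max(quant_r$library_total_mapped, 1L)
  tested <- (k_f + k_r) > 0
  zp <- proportion_test(k_f, N_f, k_r, N_r)
  q <- rep(1, length(k_f))
  if (any(tested)) {
    pi0 <- estimate_pi0(zp$p[tested], lambda = pi0_lambda)
    q[tested] <- qvalues(zp$p[tested], pi0)
  }
  out <- data.frame(
    contig_id = quant_f$counts$contig_id,
    k_f = k_f, k_r = k_r, N_f = N_f, N_r = N_r,
    rpkm_f = quant_f$counts$rpkm, rpkm_r = quant_r$counts$rpkm,
    z = zp$z, p = zp$p, q = q,
    log2fc = log2_fold_change(quant_f$counts$rpkm, quant_r$counts$rpkm),
    significant = q <= q_cut,
    stringsAsFactors = FALSE)
  class(out) <- c("ssh_diff", "data.frame")
  out
}
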