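#' Spearman cross-correlation of the JIERP across latencies
#'
#' Correlates the across-bin modulation map at every latency with the map
#' at every other latency (Spearman rank correlation over the valid bins),
#' yielding a symmetric T x T matrix with unit diagonal. Two-sided
#' p-values use the t-approximation with n - 2 degrees of freedom, where n
#' is the number of jointly valid bins. Latencies whose map is constant
#' (all ranks tied) yield undefined coefficients and are flagged.
#'
#' @param zjierp a (typically grand-averaged) `zjierp`.
#' @param min_bins minimum jointly valid bins per pair (default 5).
#' @return a `crosscorr`: list with `rho`, `p` (T x T), `time_ms`,
#'   `undefined` (logical per latency), `n_bins`.
#' @export
crosscorr_spearman <- function(zjierp, min_bins = 5) {
  stopifnot(inherits(zjierp, "zjierp"))
  b <- zjierp$grid$n_bins
  nt <- length(zjierp$time_ms)
  flat <- matrix(zjierp$z, b * b, nt)
  vf <- as.vector(zjierp$valid)
  x <- flat[vf, , drop = FALSE]            # valid bins x latencies
  n <- nrow(x)
  if (n < min_bins) stop("fewer than ", min_bins, " valid bins")
  undef <- apply(x, 2, function(col) stats::sd(col) == 0)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  diag(rho) <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  rho[undef, ] <- NA_real_; rho[, undef] <- NA_real_
  p[undef, ] <- NA_real_; p[, undef] <- NA_real_
  structure(list(rho = rho, p = p, time_ms = zjierp$time_ms,
                 undefined = undef, n_bins = n,
                 fdr_mask = NULL, excluded_band_halfwidth_ms = NULL),
            class = "crosscorr")
}

#' FDR correction of the cross-correlation matrix excluding the diagonal
#'
#' Pools the unique upper-triangle p-values whose latency separation
#' exceeds the diagonal band (|dt| > `band_halfwidth_ms`), applies
#' Benjamini-Hochberg at `alpha`, and mirrors the rejection mask to the
#' lower triangle. Entries inside the band (including the unit diagonal)
#' never enter the pool. The band parameter is a half-width; set
#' `band_halfwidth_ms` to half the desired value to interpret it as a
#' full width.
#'
#' @param ccm a `crosscorr`.
#' @param alpha FDR level (default 0.05).
#' @param band_halfwidth_ms excluded band half-width in ms (default 25).
#' @return the `crosscorr` with `fdr_mask`, `p_adj`, and the band recorded.
#' @export
fdr_offdiagonal <- function(ccm, alpha = 0.05, band_halfwidth_ms = 25) {
  stopifnot(inherits(ccm, "crosscorr"), band_halfwidth_ms >= 0)
  tm <- ccm$time_ms
  nt <- length(tm)
  dt <- abs(outer(tm, tm, "-"))
  pool <- upper.tri(dt) & dt > band_halfwidth_ms & !is.na(ccm$p)
  if (!any(pool)) stop("excluded band covers the whole matrix")
  fdr <- fdr_bh(ccm$p[pool], alpha = alpha)
  mask <- matrix(FALSE, nt, nt)
  padj <- matrix(NA_real_, nt, nt)
  mask[pool] <- fdr$mask
  padj[pool] <- fdr$p_adj
  mask <- mask | t(mask)
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  ccm$fdr_mask <- mask
  ccm$p_adj <- padj
  ccm$excluded_band_halfwidth_ms <- band_halfwidth_ms
  ccm$alpha <- alpha
  ccm
}

#' Mean off-band cross-correlation between two latency stages
#'
#' Averages `rho` over all latency pairs (t1 in `win_a`, t2 in `win_b`)
#' whose separation exceeds the excluded band — the summary used to
#' contrast early/late similarity against the intermediate stage.
#'
#' @param ccm a `crosscorr`.
#' @param win_a,win_b ms windows, e.g. `c(1, 75)` and `c(150, 300)`.
#' @param band_halfwidth_ms pairs with |dt| <= this are skipped.
#' @return mean Spearman rho over the selected pairs.
#' @export
stage_mean_rho <- function(ccm, win_a, win_b, band_halfwidth_ms = 25) {
  stopifnot(inherits(ccm, "crosscorr"))
  ia <- which(ccm$time_ms >= win_a[1] & ccm$time_ms <= win_a[2])
  ib <- which(ccm$time_ms >= win_b[1] & ccm$time_ms <= win_b[2])
  dt <- abs(outer(ccm$time_ms[ia], ccm$time_ms[ib], "-"))
  vals <- ccm$rho[ia, ib, drop = FALSE]
  mean(vals[dt > band_halfwidth_ms], na.rm = TRUE)
}
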