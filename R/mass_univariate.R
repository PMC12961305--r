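#' Mass-univariate one-sample t-tests on z-scored JIERPs
#'
#' At every bin x latency cell, tests the across-subject z-scores against
#' zero (two-sided). A subject contributes to a cell iff that bin is valid
#' in its JIERP. Cells with fewer than `min_subjects` contributors are
#' flagged untested; cells with zero variance across subjects are flagged
#' degenerate (t = 0, p = 1). Multiple comparisons are corrected jointly
#' across the entire JIERP with [fdr_bh()].
#'
#' @param z_jierps list of per-subject `zjierp` objects (compatible grids).
#' @param alpha FDR level (default 0.05).
#' @param min_subjects minimum contributing subjects per cell (default 3).
#' @param method `"BH"` (default) or `"BY"`.
#' @return a `stat_map`: list with arrays `t`, `p`, `p_adj`, `fdr_mask`,
#'   `n_subjects` (b x b), `tested`, `degenerate`, `alpha`, `time_ms`.
#' @export
bin_ttest <- function(z_jierps, alpha = 0.05, min_subjects = 3,
                      method = c("BH", "BY")) {
  method <- match.arg(method)
  stopifnot(length(z_jierps) >= min_subjects,
            all(vapply(z_jierps, inherits, TRUE, "zjierp")))
  tm <- z_jierps[[1]]$time_ms
  b <- z_jierps[[1]]$grid$n_bins
  nt <- length(tm)
  ns <- length(z_jierps)
  tmat <- matrix(NA_real_, b * b, nt)
  pmat <- matrix(NA_real_, b * b, nt)
  degmat <- matrix(FALSE, b * b, nt)
  nsub <- matrix(0L, b, b)
  zs <- lapply(z_jierps, function(z) matrix(z$z, b * b, nt))
  vs <- vapply(z_jierps, function(z) as.vector(z$valid),
               logical(b * b))          # (b*b) x ns
  for (cell in seq_len(b * b)) {
    contrib <- which(vs[cell, ])
    nsub[cell] <- length(contrib)
    if (length(contrib) < min_subjects) next
    X <- do.call(rbind, lapply(zs[contrib], function(m) m[cell, ]))
    n <- nrow(X)
    mu <- colMeans(X)
    s <- sqrt(colSums(sweep(X, 2, mu)^2) / (n - 1))
    deg <- s == 0
    tt <- ifelse(deg, 0, mu / (ifelse(deg, 1, s) / sqrt(n)))
    pp <- ifelse(deg, 1, 2 * stats::pt(-abs(tt), df = n - 1))
    tmat[cell, ] <- tt
    pmat[cell, ] <- pp
    degmat[cell, ] <- deg
  }
  tested <- !is.na(pmat)
  fdr <- fdr_bh(pmat[tested], alpha = alpha, method = method)
  padj <- matrix(NA_real_, b * b, nt)
  mask <- matrix(FALSE, b * b, nt)
  padj[tested] <- fdr$p_adj
  mask[tested] <- fdr$mask
  dims <- c(b, b, nt)
  structure(list(t = array(tmat, dims), p = array(pmat, dims),
                 p_adj = array(padj, dims), fdr_mask = array(mask, dims),
                 n_subjects = nsub, tested = array(tested, dims),
                 degenerate = array(degmat, dims),
                 alpha = alpha, time_ms = tm,
                 meta = list(method = method, n_input_subjects = ns,
                             min_subjects = min_subjects)),
            class = "stat_map")
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up control of the FDR on a flat vector of p-values; the mask marks
#' rejections at level `alpha` (adjusted p <= alpha). `"BY"` applies the
#' dependence-adjusted Benjamini-Yekutieli variant.
#'
#' @param p numeric p-values in `[0, 1]` (NA allowed, never rejected).
#' @param alpha level, default 0.05.
#' @param method `"BH"` or `"BY"`.
#' @return list with `mask` (logical) and `p_adj` (monotone adjusted p).
#' @export
fdr_bh <- function(p, alpha = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p) == 0)
    return(list(mask = logical(0), p_adj = numeric(0)))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p_adj <- stats::p.adjust(p, method = method)
  list(mask = !is.na(p_adj) & p_adj <= alpha, p_adj = p_adj)
}

#' Mean false-discovery proportion under a global-null simulation
#'
#' Draws `n_reps` independent datasets of `n_subjects` z-scored JIERPs
#' whose cells are i.i.d. standard normal (no planted effect), runs
#' [bin_ttest()] with joint FDR correction on each, and returns the mean
#' false-discovery proportion (every discovery under the null is false;
#' FDP = 1 if any cell is rejected in a replicate, else 0).
#'
#' @param n_reps replicates (default 200).
#' @param n_subjects subjects per replicate (default 30).
#' @param n_latencies post-stimulus latencies (default 299).
#' @param grid a [bin_grid()].
#' @param alpha FDR level.
#' @param seed integer seed.
#' @return list with `mean_fdp`, per-replicate `fdp`, `n_cells`.
#' @export
null_fdp_simulation <- function(n_reps = 200, n_subjects = 30,
                                n_latencies = 299, grid = bin_grid(),
                                alpha = 0.05, seed = 1L) {
  b <- grid$n_bins
  tm <- seq_len(n_latencies)
  fdp <- withr::with_seed(seed, vapply(seq_len(n_reps), function(r) {
    zs <- lapply(seq_len(n_subjects), function(s) {
      structure(list(z = array(stats::rnorm(b * b * n_latencies),
                               dim = c(b, b, n_latencies)),
                     valid = matrix(TRUE, b, b), time_ms = tm,
                     constant_latency = rep(FALSE, n_latencies),
                     grid = grid, meta = list()),
                class = "zjierp")
    })
    sm <- bin_ttest(zs, alpha = alpha)
    n_rej <- sum(sm$fdr_mask)
    if (n_rej > 0) 1 else 0   # all rejections are false under the null
  }, numeric(1)))
  list(mean_fdp = mean(fdp), fdp = fdp,
       n_cells = as.integer(b * b * n_latencies))
}

#' Tabulate FDR-significant cells
#'
#' @param sm a `stat_map`.
#' @return data.frame with one row per significant cell: `row`, `col`,
#'   `time_ms`, `t`, `p_adj`, `sign`.
#' @export
significant_cells <- function(sm) {
  stopifnot(inherits(sm, "stat_map"))
  idx <- which(sm$fdr_mask, arr.ind = TRUE)
  data.frame(row = idx[, 1], col = idx[, 2],
             time_ms = sm$time_ms[idx[, 3]],
             t = sm$t[sm$fdr_mask], p_adj = sm$p_adj[sm$fdr_mask],
             sign = ifelse(sm$t[sm$fdr_mask] > 0, "enhanced", "suppressed"))
}
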