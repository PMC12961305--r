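#' Planted meta-JIERP / meta-time pattern library
#'
#' Three prototypical factor pairs emulating the structure reported for
#' somatosensory JIERPs, defined on the 5 x 5 joint-interval grid
#' (25-element meta-JIERPs, bin order column-major: row = penultimate,
#' col = previous interval) and 299 post-stimulus latencies:
#' \describe{
#'   \item{1}{meta-JIERP low for previous intervals < 1 s and high above
#'     2 s; meta-time with humps in the early and late stages.}
#'   \item{2}{meta-JIERP high for intermediate previous intervals
#'     (0.5-4 s); meta-time peaking early with a second intermediate
#'     peak.}
#'   \item{3}{meta-JIERP high for short previous intervals (< 0.5 s);
#'     meta-time with a single intermediate-stage hump.}
#' }
#'
#' @param grid a [bin_grid()].
#' @param n_latencies post-stimulus latencies (default 299, t = 1..299 ms).
#' @return list with `W` (25 x 3, columns unit-normalized), `H` (3 x 299,
#'   rows unit-normalized), `time_ms`.
#' @export
planted_patterns <- function(grid = bin_grid(), n_latencies = 299) {
  ctr <- bin_centers(grid)                  # per-axis bin centers, s
  b <- grid$n_bins
  k_col <- rep(ctr, each = b)               # previous interval per cell
  ramp_up <- function(x, mid, slope = 0.2)
    stats::plogis((log10(x) - log10(mid)) / slope)
  w1 <- 0.1 + 0.9 * ramp_up(k_col, 1.5)            # low < 1 s, high > 2 s
  w2 <- 0.15 + 0.85 * exp(-(log10(k_col) - log10(1.4))^2 / 0.25)
  w3 <- 0.1 + 0.9 * (1 - ramp_up(k_col, 0.7, 0.15)) # high < 0.5 s
  t <- seq_len(n_latencies)
  bump <- function(mu, sg) exp(-(t - mu)^2 / (2 * sg^2))
  h1 <- bump(40, 16) + bump(220, 40)
  h2 <- bump(55, 18) + 0.7 * bump(110, 18)
  h3 <- bump(115, 22)
  unitc <- function(M) sweep(M, 2, sqrt(colSums(M^2)), "/")
  unitr <- function(M) sweep(M, 1, sqrt(rowSums(M^2)), "/")
  list(W = unitc(cbind(w1, w2, w3)), H = unitr(rbind(h1, h2, h3)),
       time_ms = t)
}

#' Simulate subject-level JIERP magnitude matrices from planted patterns
#'
#' Each subject's 25 x 299 matrix is the planted low-rank product
#' `W diag(a_s) H` with subject-specific factor amplitudes, plus Gaussian
#' noise scaled to a fraction of the signal Frobenius norm, truncated at
#' zero so the matrix stays non-negative.
#'
#' @param n_subjects number of subjects (default 20).
#' @param noise_frac noise Frobenius norm as a fraction of the signal
#'   norm (default 0.1).
#' @param amp_sd SD of the log-normal subject amplitude jitter
#'   (default 0.15).
#' @param patterns output of [planted_patterns()].
#' @param seed integer seed.
#' @return list with `matrices` (list of 25 x 299 matrices), `patterns`.
#' @export
simulate_planted_subjects <- function(n_subjects = 20, noise_frac = 0.1,
                                      amp_sd = 0.15,
                                      patterns = planted_patterns(),
                                      seed = 1L) {
  W <- patterns$W; H <- patterns$H
  r <- ncol(W)
  mats <- withr::with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    a <- exp(stats::rnorm(r, sd = amp_sd))
    S <- W %*% (a * H)
    sig <- sqrt(sum(S^2))
    E <- matrix(stats::rnorm(length(S)), nrow(S))
    E <- E * (noise_frac * sig / sqrt(sum(E^2)))
    pmax(S + E, 0)
  }))
  list(matrices = mats, patterns = patterns)
}

#' Planted-pattern recovery study
#'
#' Runs the individual-level decomposition arm of the pipeline on
#' simulated subjects: stability-selected NNMF at the planted rank per
#' subject, factor normalization, pooling, k-means clustering of
#' meta-times with silhouette-selected k, and cluster-averaged
#' representatives. Each representative is matched one-to-one to a
#' planted pattern (optimal assignment on meta-time correlation) and the
#' match quality is reported.
#'
#' @param n_subjects subjects (default 20).
#' @param noise_frac noise fraction (default 0.1).
#' @param n_reps stability repetitions per subject (default 50).
#' @param k_range cluster search range (default 3:7).
#' @param n_restarts k-means restarts (default 200).
#' @param seed integer seed.
#' @return list with `solution`, `representatives`, `matching`
#'   (data.frame cluster / pattern / metatime_r / metajierp_cos), `k`.
#' @export
planted_recovery_study <- function(n_subjects = 20, noise_frac = 0.1,
                                   n_reps = 50, k_range = 3:7,
                                   n_restarts = 200, seed = 1L) {
  sim <- simulate_planted_subjects(n_subjects, noise_frac, seed = seed)
  r <- ncol(sim$patterns$W)
  fits <- lapply(seq_along(sim$matrices), function(s)
    normalize_factors(stable_factorize(sim$matrices[[s]], rank = r,
                                       n_reps = n_reps,
                                       seed = seed + 7L * s)))
  pooled <- pool_factors(fits)
  sol <- cluster_metatimes(pooled$metatimes, k_range = k_range,
                           n_restarts = n_restarts, seed = seed)
  reps <- cluster_representatives(sol, pooled)
  # match representatives to planted patterns on meta-time correlation
  n_match <- min(length(reps), r)
  C <- matrix(0, length(reps), r)
  for (i in seq_along(reps)) for (j in seq_len(r))
    C[i, j] <- stats::cor(reps[[i]]$metatime, sim$patterns$H[j, ])
  matching <- if (length(reps) == r) {
    asg <- assignment_min_cost(-C)$assignment
    data.frame(cluster = seq_along(reps), pattern = asg)
  } else {
    data.frame(cluster = seq_along(reps),
               pattern = apply(C, 1, which.max))
  }
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  matching$metatime_r <- vapply(seq_len(nrow(matching)), function(i)
    C[matching$cluster[i], matching$pattern[i]], numeric(1))
  matching$metajierp_cos <- vapply(seq_len(nrow(matching)), function(i)
    cosv(reps[[matching$cluster[i]]]$metajierp,
         sim$patterns$W[, matching$pattern[i]]), numeric(1))
  list(solution = sol, representatives = reps, matching = matching,
       k = sol$k, pooled = pooled, patterns = sim$patterns)
}
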