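#' Triads: previous and penultimate intervals per stimulation
#'
#' From the third event of a train onward, each stimulus is attributed the
#' previous interval `k = onset[i] - onset[i-1]` and the penultimate
#' interval `k_minus_1 = onset[i-1] - onset[i-2]`, both in seconds.
#'
#' @param train a `stim_train`.
#' @return data.frame with columns `event_index`, `k`, `k_minus_1`
#'   (empty if fewer than 3 events).
#' @export
compute_triads <- function(train) {
  stopifnot(inherits(train, "stim_train"))
  on <- train$onsets
  n <- length(on)
  if (n < 3)
    return(data.frame(event_index = integer(), k = numeric(),
                      k_minus_1 = numeric()))
  i <- 3:n
  data.frame(event_index = i,
             k = (on[i] - on[i - 1]) / 1000,
             k_minus_1 = (on[i - 1] - on[i - 2]) / 1000)
}

#' Joint-interval bin grid
#'
#' A square grid over (penultimate, previous) interval pairs with the
#' stated upper bin edges; the first bin opens at 0 s. Membership is
#' half-open `(lower, upper]` (upper-bound inclusive). Intervals above the
#' largest edge are excluded.
#'
#' @param upper_edges strictly increasing upper bounds in seconds,
#'   default `c(0.5, 1, 2, 4, 8)`.
#' @return a `bin_grid` object.
#' @export
bin_grid <- function(upper_edges = c(0.5, 1, 2, 4, 8)) {
  stopifnot(length(upper_edges) >= 1, all(diff(upper_edges) > 0),
            all(upper_edges > 0))
  structure(list(upper_edges = upper_edges, n_bins = length(upper_edges)),
            class = "bin_grid")
}

#' Geometric centers of the grid bins (seconds), for plotting and presets
#' @param grid a [bin_grid()].
#' @return numeric vector of per-axis bin centers.
#' @export
bin_centers <- function(grid) {
  lo <- c(grid$upper_edges[1] / 2, grid$upper_edges[-grid$n_bins])
  sqrt(lo * grid$upper_edges)
}

#' Assign triads to joint-interval bins
#'
#' An interval maps to the smallest bin whose upper edge it does not
#' exceed; a triad is excluded if either interval exceeds the largest
#' edge. Convention: row = penultimate interval (k-1), column = previous
#' interval (k), both 1-based.
#'
#' @param triads data.frame from [compute_triads()].
#' @param grid a [bin_grid()].
#' @return data.frame `triads` with integer columns `row`, `col`
#'   (NA when excluded).
#' @export
assign_bin <- function(triads, grid = bin_grid()) {
  stopifnot(inherits(grid, "bin_grid"))
  if (any(triads$k <= 0 | triads$k_minus_1 <= 0, na.rm = TRUE))
    stop("non-positive interval")
  edge <- grid$upper_edges
  ix <- function(x) {
    b <- findInterval(x, edge, left.open = TRUE) + 1L  # (lower, upper]
    b[x > edge[length(edge)]] <- NA_integer_
    b
  }
  triads$row <- ix(triads$k_minus_1)
  triads$col <- ix(triads$k)
  excl <- is.na(triads$row) | is.na(triads$col)
  triads$row[excl] <- NA_integer_
  triads$col[excl] <- NA_integer_
  triads
}

#' Build the JIERP tensor
#'
#' Pools the retained single-trial epochs of one channel by joint-interval
#' bin and averages them; bins with fewer than `min_trials` contributing
#' trials are flagged invalid (their amplitude is NA). Trial accounting
#' (per-bin counts, exclusions beyond the largest edge, rejected/dropped
#' epochs, the first two events) is stored in `counts`.
#'
#' @param epochs an `epoch_set` aligned to the train behind `triads`.
#' @param triads output of [compute_triads()] on the same train.
#' @param channel channel index (e.g. from [select_channel()]).
#' @param grid a [bin_grid()].
#' @param min_trials minimum trials per bin for a valid ERP (default 10).
#' @return a `jierp` object: list with `amplitude` (5 x 5 x T array, uV;
#'   NA where invalid), `trial_count`, `valid`, `time_ms`, `grid`,
#'   `counts`, `meta`.
#' @export
build_jierp <- function(epochs, triads, channel = 1L, grid = bin_grid(),
                        min_trials = 10) {
  stopifnot(inherits(epochs, "epoch_set"))
  asg <- assign_bin(triads, grid)
  b <- grid$n_bins
  nt <- length(epochs$time_ms)
  total <- matrix(0, b * b, nt)
  cnt <- matrix(0L, b, b)
  n_excl_edge <- 0L
  n_unavailable <- 0L  # rejected or edge-dropped epochs
  pos <- match(asg$event_index, epochs$event_index)
  for (j in seq_len(nrow(asg))) {
    if (is.na(asg$row[j])) { n_excl_edge <- n_excl_edge + 1L; next }
    pj <- pos[j]
    if (is.na(pj) || epochs$rejected[pj]) { n_unavailable <- n_unavailable + 1L; next }
    cell <- (asg$col[j] - 1L) * b + asg$row[j]
    total[cell, ] <- total[cell, ] + epochs$data[pj, channel, ]
    cnt[asg$row[j], asg$col[j]] <- cnt[asg$row[j], asg$col[j]] + 1L
  }
  valid <- cnt >= min_trials
  if (!any(valid))
    stop("no valid bins: max trial count ", max(cnt),
         " < min_trials ", min_trials)
  amp <- array(NA_real_, dim = c(b, b, nt))
  for (r in seq_len(b)) for (cc in seq_len(b)) {
    if (cnt[r, cc] > 0)
      amp[r, cc, ] <- total[(cc - 1L) * b + r, ] / cnt[r, cc]
    if (!valid[r, cc]) amp[r, cc, ] <- NA_real_
  }
  structure(list(amplitude = amp, trial_count = cnt, valid = valid,
                 time_ms = epochs$time_ms, grid = grid,
                 counts = list(total_events = length(epochs$events$onsets),
                               first_two = 2L,
                               excluded_over_edge = n_excl_edge,
                               unavailable_epochs = n_unavailable,
                               pooled = sum(cnt)),
                 meta = list(channel = channel, min_trials = min_trials,
                             axis = "row = penultimate (k-1), col = previous (k)")),
            class = "jierp")
}

#' Grand-average JIERPs across subjects
#'
#' Per bin and latency, the mean over subjects whose bin is valid; a grand
#' bin is valid iff at least `min_subject_fraction` of subjects contribute.
#'
#' @param jierps non-empty list of compatible `jierp` objects.
#' @param min_subject_fraction fraction of subjects required per bin
#'   (default 0.8).
#' @return a `jierp` with `trial_count` holding contributing-subject counts.
#' @export
grand_average <- function(jierps, min_subject_fraction = 0.8) {
  stopifnot(length(jierps) >= 1,
            all(vapply(jierps, inherits, TRUE, "jierp")))
  tm <- jierps[[1]]$time_ms
  b <- jierps[[1]]$grid$n_bins
  for (j in jierps) stopifnot(identical(j$time_ms, tm),
                              j$grid$n_bins == b)
  nsub <- length(jierps)
  sumamp <- array(0, dim = c(b, b, length(tm)))
  nvalid <- matrix(0L, b, b)
  for (j in jierps) {
    a <- j$amplitude
    a[is.na(a)] <- 0
    sumamp <- sumamp + a
    nvalid <- nvalid + j$valid
  }
  valid <- nvalid >= ceiling(min_subject_fraction * nsub)
  amp <- sumamp / array(nvalid, dim = dim(sumamp))
  amp[array(!valid | nvalid == 0, dim = dim(amp))] <- NA_real_
  structure(list(amplitude = amp, trial_count = nvalid, valid = valid,
                 time_ms = tm, grid = jierps[[1]]$grid,
                 counts = list(n_subjects = nsub),
                 meta = list(source = "grand-average",
                             min_subject_fraction = min_subject_fraction)),
            class = "jierp")
}

#' z-score a JIERP across bins at each latency
#'
#' At every latency, the valid-bin amplitudes are standardized to mean 0
#' and sample SD 1 (denominator n-1). Latencies where the SD is zero get
#' all-zero z-values and are flagged in `constant_latency`.
#'
#' @param jierp a `jierp` with at least 2 valid bins.
#' @return a `zjierp`: list with `z` (b x b x T), `valid`, `time_ms`,
#'   `constant_latency` (logical per latency), `grid`, `meta`.
#' @export
zscore_latencywise <- function(jierp) {
  stopifnot(inherits(jierp, "jierp"))
  v <- jierp$valid
  if (sum(v) < 2) stop("need at least 2 valid bins to z-score")
  b <- jierp$grid$n_bins
  nt <- length(jierp$time_ms)
  flat <- matrix(jierp$amplitude, b * b, nt)   # bins x latencies
  vf <- as.vector(v)
  x <- flat[vf, , drop = FALSE]
  mu <- colMeans(x)
  sdv <- sqrt(colSums(sweep(x, 2, mu)^2) / (nrow(x) - 1))
  const <- sdv == 0
  z <- sweep(sweep(x, 2, mu), 2, ifelse(const, 1, sdv), "/")
  z[, const] <- 0
  zfull <- matrix(NA_real_, b * b, nt)
  zfull[vf, ] <- z
  structure(list(z = array(zfull, dim = c(b, b, nt)), valid = v,
                 time_ms = jierp$time_ms, constant_latency = const,
                 grid = jierp$grid,
                 meta = c(jierp$meta, list(zscored = TRUE))),
            class = "zjierp")
}
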