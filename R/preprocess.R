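#' Zero-phase FIR band-pass filter
#'
#' Designs a Hamming-window FIR band-pass (`signal::fir1`) and applies it
#' as a delay-compensated linear-phase pass via FFT convolution, so
#' component latencies are not shifted. The filter order follows the
#' common heuristic of ~3.3 cycles of the narrower transition band
#' (transition width: `min(max(0.25*edge, 2), edge)` at the low edge and
#' `min(max(0.25*edge, 2), nyquist - edge)` at the high edge). The signal
#' is reflection-padded by the filter length so edge transients do not
#' leak into the data.
#'
#' @param rec an `eeg_recording`.
#' @param low,high passband edges in Hz, `0 < low < high < srate/2`.
#' @param order optional FIR order override (even integer).
#' @return the filtered recording; `meta$filters` records the applied band.
#' @export
bandpass <- function(rec, low = 1, high = 45, order = NULL) {
  stopifnot(inherits(rec, "eeg_recording"),
            low > 0, high > low)
  fs <- rec$srate
  if (high >= fs / 2) stop("passband infeasible at srate ", fs)
  if (is.null(order)) {
    tw <- min(min(max(0.25 * low, 2), low),
              min(max(0.25 * high, 2), fs / 2 - high))
    order <- ceiling(3.3 * fs / tw)
    if (order %% 2 == 1) order <- order + 1
  }
  n <- ncol(rec$data)
  if (n <= order + 2)
    stop("recording too short for a filter of order ", order)
  b <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  rec$data <- t(apply(rec$data, 1, fir_zerophase, b = b))
  rec$meta$filters <- c(rec$meta$filters,
                        list(list(low = low, high = high, order = order)))
  rec
}

# delay-compensated FIR filtering with reflection padding, FFT convolution
fir_zerophase <- function(x, b) {
  L <- length(b)
  p <- L                                  # pad length each side
  xp <- c(2 * x[1] - rev(x[2:(p + 1)]), x,
          2 * x[length(x)] - rev(x[(length(x) - p):(length(x) - 1)]))
  nfft <- stats::nextn(length(xp) + L - 1, 2)
  y <- Re(stats::fft(stats::fft(c(xp, numeric(nfft - length(xp)))) *
                       stats::fft(c(b, numeric(nfft - L))),
                     inverse = TRUE)) / nfft
  d <- (L - 1) / 2                        # group delay of linear-phase FIR
  y[(p + d + 1):(p + d + length(x))]
}

#' Cut fixed-length epochs around stimulus onsets
#'
#' One epoch per event whose full window fits inside the recording; the
#' sample at t = 0 is aligned to the event onset. Events too close to the
#' recording edges are dropped and counted.
#'
#' @param rec an `eeg_recording`.
#' @param window epoch window in ms, default `c(-200, 299)` (500 samples).
#' @return An `epoch_set`: list with `data` (n_epochs x n_channels x
#'   n_samples array, uV), `time_ms`, `event_index` (into the train),
#'   `rejected` (logical, all FALSE here), `n_dropped_edge`,
#'   `channel_labels`, `events`, `meta`.
#' @export
epoch_events <- function(rec, window = c(-200, 299)) {
  stopifnot(inherits(rec, "eeg_recording"), length(window) == 2,
            window[1] < window[2])
  time_ms <- window[1]:window[2]
  onsets <- rec$events$onsets
  n <- ncol(rec$data)
  # sample index of time t ms relative to event: onset + t + 1 (1-based)
  ok <- (onsets + window[1] + 1) >= 1 & (onsets + window[2] + 1) <= n
  keep <- which(ok)
  data <- array(NA_real_, dim = c(length(keep), nrow(rec$data),
                                  length(time_ms)))
  for (j in seq_along(keep)) {
    idx <- onsets[keep[j]] + time_ms + 1
    data[j, , ] <- rec$data[, idx, drop = FALSE]
  }
  structure(list(data = data, time_ms = time_ms,
                 event_index = keep,
                 rejected = rep(FALSE, length(keep)),
                 n_dropped_edge = sum(!ok),
                 channel_labels = rec$channel_labels,
                 events = rec$events,
                 meta = c(rec$meta, list(window_ms = window,
                                         steps = "epoch"))),
            class = "epoch_set")
}

#' Mark epochs exceeding an absolute amplitude threshold
#'
#' Epochs whose maximum absolute amplitude on any channel strictly exceeds
#' the threshold are flagged rejected ("beyond" the bound); epochs exactly
#' at the boundary are retained.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection bound in uV (default 80).
#' @return the epoch set with `rejected` updated.
#' @export
reject_amplitude <- function(epochs, threshold_uv = 80) {
  stopifnot(inherits(epochs, "epoch_set"), threshold_uv > 0)
  peak <- apply(abs(epochs$data), 1, max)
  epochs$rejected <- epochs$rejected | (peak > threshold_uv)
  epochs$meta$steps <- c(epochs$meta$steps, "reject")
  epochs$meta$reject_uv <- threshold_uv
  epochs
}

#' Re-reference epochs to the scalp average
#'
#' Subtracts, at every sample, the mean across channels, so the channel
#' mean is zero everywhere. Idempotent.
#'
#' @param epochs an `epoch_set` with at least 2 channels.
#' @return the re-referenced epoch set.
#' @export
average_reference <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[2] < 2)
    stop("average reference undefined for a single channel")
  m <- apply(epochs$data, c(1, 3), mean)
  epochs$data <- epochs$data - aperm(
    array(m, dim = dim(epochs$data)[c(1, 3, 2)]), c(1, 3, 2))
  epochs$meta$steps <- c(epochs$meta$steps, "reference")
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window so
#' the baseline mean is zero. Idempotent.
#'
#' @param epochs an `epoch_set`.
#' @param window baseline window in ms, default `c(-200, -50)`.
#' @return the corrected epoch set.
#' @export
baseline_correct <- function(epochs, window = c(-200, -50)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$time_ms >= window[1] & epochs$time_ms <= window[2]
  if (!any(sel)) stop("baseline window outside epoch time axis")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(bl, dim = dim(epochs$data))
  epochs$meta$steps <- c(epochs$meta$steps, "baseline")
  epochs$meta$baseline_ms <- window
  epochs
}

#' Select the analysis electrode from a region of interest
#'
#' Averages retained epochs per ROI channel and returns the channel whose
#' ERP attains the largest criterion value inside the latency window:
#' the maximum positive amplitude (default, targeting the P50 positivity)
#' or the maximum absolute amplitude. Ties go to the lowest channel index.
#'
#' @param epochs an `epoch_set`.
#' @param latency_window ms window, default `c(25, 75)`; use `c(150, 300)`
#'   for the central electrode.
#' @param roi channel indices or labels to search (non-empty).
#' @param criterion `"max_positive"` or `"max_abs"`.
#' @return integer channel index (attribute `"criterion_value"` holds the
#'   winning value).
#' @export
select_channel <- function(epochs, latency_window = c(25, 75),
                           roi = seq_len(dim(epochs$data)[2]),
                           criterion = c("max_positive", "max_abs")) {
  stopifnot(inherits(epochs, "epoch_set"), length(roi) > 0)
  criterion <- match.arg(criterion)
  if (is.character(roi)) roi <- match(roi, epochs$channel_labels)
  stopifnot(!anyNA(roi))
  roi <- sort(unique(as.integer(roi)))   # ties break to the lowest index
  keep <- !epochs$rejected
  if (!any(keep)) stop("no retained epochs")
  sel <- epochs$time_ms >= latency_window[1] &
    epochs$time_ms <= latency_window[2]
  if (!any(sel)) stop("latency window outside epoch")
  erp <- apply(epochs$data[keep, roi, sel, drop = FALSE], c(2, 3), mean)
  val <- if (criterion == "max_positive") apply(erp, 1, max)
         else apply(abs(erp), 1, max)
  ch <- roi[which.max(val)]   # which.max takes the first (lowest) on ties
  structure(as.integer(ch), criterion_value = max(val), criterion = criterion)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: band-pass filter, epoching, amplitude rejection,
#' average re-referencing, baseline correction. The applied order is
#' recorded in the output metadata. A two-stage filter (0.1-75 Hz then
#' 1-45 Hz) can be requested via `two_stage = TRUE`; the default is the
#' single 1-45 Hz pass.
#'
#' @param rec an `eeg_recording`.
#' @param low,high final passband edges in Hz.
#' @param two_stage apply a 0.1-75 Hz pass first.
#' @param epoch_window,baseline_window ms windows.
#' @param reject_uv rejection threshold, uV.
#' @return an `epoch_set` ready for JIERP construction.
#' @export
preprocess <- function(rec, low = 1, high = 45, two_stage = FALSE,
                       epoch_window = c(-200, 299),
                       baseline_window = c(-200, -50), reject_uv = 80) {
  if (two_stage) rec <- bandpass(rec, 0.1, 75)
  rec <- bandpass(rec, low, high)
  ep <- epoch_events(rec, epoch_window)
  ep <- reject_amplitude(ep, reject_uv)
  ep <- average_reference(ep)
  ep <- baseline_correct(ep, baseline_window)
  ep$meta$pipeline_order <- c("filter", "epoch", "reject", "reference",
                              "baseline")
  ep
}
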