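#' Generate a tactile stimulation train
#'
#' Draws `n_events` stimulus onsets whose inter-onset intervals are sampled
#' i.i.d. from a named distribution truncated to `interval_range`. The
#' default log-uniform law spreads intervals evenly on a logarithmic axis,
#' so the quadratic joint-interval bins (upper edges 0.5, 1, 2, 4, 8 s)
#' receive roughly balanced trial counts.
#'
#' Onsets are rounded to integer milliseconds to match a 1 kHz sampling
#' grid; rounding never pushes an interval outside `interval_range`.
#'
#' @param n_events number of stimuli (>= 3 so at least one triad exists).
#' @param interval_range numeric length-2, interval bounds in ms.
#' @param distribution `"log-uniform"` (default) or `"uniform"`.
#' @param finger label for the stimulated fingertip
#'   (`"thumb"`, `"index"` or `"little"`).
#' @param block integer block id stored with every event.
#' @param seed integer seed; the train is reproducible given the seed.
#' @return A `stim_train` object: list with `onsets` (ms, strictly
#'   increasing), `finger`, `block`, `seed`.
#' @export
generate_train <- function(n_events = 1800, interval_range = c(100, 10000),
                           distribution = c("log-uniform", "uniform"),
                           finger = "index", block = 1L, seed = 1L) {
  stopifnot(n_events >= 3, length(interval_range) == 2,
            interval_range[1] > 0, interval_range[2] > interval_range[1])
  distribution <- match.arg(distribution)
  finger <- match.arg(finger, c("thumb", "index", "little"))
  draw <- function(n) {
    u <- stats::runif(n)
    if (distribution == "log-uniform") {
      exp(log(interval_range[1]) + u * diff(log(interval_range)))
    } else {
      interval_range[1] + u * diff(interval_range)
    }
  }
  intervals <- withr::with_seed(seed, draw(n_events - 1))
  # round to the 1 kHz grid without leaving the configured range
  intervals <- pmin(pmax(round(intervals), ceiling(interval_range[1])),
                    floor(interval_range[2]))
  structure(list(onsets = cumsum(c(0, intervals)),
                 finger = finger,
                 block = rep(as.integer(block), length.out = n_events),
                 seed = as.integer(seed)),
            class = "stim_train")
}

#' Somatosensory evoked-potential template
#'
#' Builds a smooth evoked waveform on a 0..299 ms latency grid as a sum of
#' Gaussian-windowed components. The default preset reproduces the canonical
#' fingertip response: peaks near 50 (+), 75 (-), 100 (+), 150 (-) and
#' 200 (+) ms with alternating polarity. The waveform is anchored to zero
#' at latency 0.
#'
#' @param component_peaks data.frame with columns `latency_ms`,
#'   `amplitude_uv` (signed; sign encodes polarity) and optional `sigma_ms`
#'   (Gaussian half-width, default scales with latency). Rows must be sorted
#'   by latency and lie within the grid.
#' @param latency_grid integer ms grid, default `0:299`.
#' @return An `erp_template`: list with `latencies`, `amplitude` (uV) and
#'   `component_peaks`.
#' @export
erp_template <- function(component_peaks = default_component_peaks(),
                         latency_grid = 0:299) {
  stopifnot(is.data.frame(component_peaks))
  if (nrow(component_peaks) > 0) {
    stopifnot(!is.unsorted(component_peaks$latency_ms),
              all(component_peaks$latency_ms >= min(latency_grid)),
              all(component_peaks$latency_ms <= max(latency_grid)))
  }
  if (is.null(component_peaks$sigma_ms))
    component_peaks$sigma_ms <- pmax(6, component_peaks$latency_ms * 0.09)
  w <- numeric(length(latency_grid))
  for (i in seq_len(nrow(component_peaks))) {
    w <- w + component_peaks$amplitude_uv[i] *
      exp(-(latency_grid - component_peaks$latency_ms[i])^2 /
            (2 * component_peaks$sigma_ms[i]^2))
  }
  w <- w - w[1]  # anchor: zero amplitude at latency 0
  structure(list(latencies = latency_grid, amplitude = w,
                 component_peaks = component_peaks),
            class = "erp_template")
}

#' @rdname erp_template
#' @export
default_component_peaks <- function() {
  data.frame(latency_ms = c(50, 75, 100, 150, 200),
             amplitude_uv = c(4, -3, 3.5, -4, 5),
             sigma_ms = c(7, 7, 9, 13, 17))
}

# latency windows naming the processing stages (ms, post-stimulus)
stage_windows <- function() {
  list(early = c(1, 75), intermediate = c(75, 150), late = c(150, 300))
}

#' Interval-conditioned modulation specification
#'
#' A `modulation_spec` maps a triad's previous interval `k` and penultimate
#' interval `k_minus_1` (seconds) plus a latency window name to a
#' multiplicative gain applied to the evoked template. Presets:
#' \describe{
#'   \item{none}{gain 1 everywhere.}
#'   \item{early_late_suppression}{in the early and late windows the gain
#'     depends on `k` only: below 1 for `k` < 0.5 s, above 1 for `k` > 2 s
#'     (suppression after short previous intervals, enhancement after long
#'     ones). The intermediate window depends on both intervals, with
#'     larger gain after short `k` and short `k_minus_1`.}
#'   \item{diagonal}{gain monotone increasing in `min(k, k_minus_1)` in all
#'     windows: small for consecutive short intervals, large for
#'     consecutive long ones.}
#' }
#' @param preset one of `"none"`, `"early_late_suppression"`, `"diagonal"`.
#' @return A `modulation_spec` object.
#' @export
modulation_spec <- function(preset = c("none", "early_late_suppression",
                                       "diagonal")) {
  preset <- match.arg(preset)
  structure(list(preset = preset), class = "modulation_spec")
}

#' Evaluate the modulation gain for one triad
#'
#' @param k previous interval, seconds (> 0).
#' @param k_minus_1 penultimate interval, seconds (> 0).
#' @param latency_window `"early"`, `"intermediate"` or `"late"`.
#' @param spec a [modulation_spec()].
#' @return scalar gain, finite and non-negative.
#' @export
modulation_gain <- function(k, k_minus_1, latency_window, spec) {
  stopifnot(inherits(spec, "modulation_spec"), k > 0, k_minus_1 > 0)
  latency_window <- match.arg(latency_window,
                              c("early", "intermediate", "late"))
  # logistic ramp in log10-interval; s(x) -> 1 for short x, 0 for long x
  short <- function(x, mid = 1, slope = 0.15)
    stats::plogis(-(log10(x) - log10(mid)) / slope)
  switch(spec$preset,
    none = 1,
    early_late_suppression = {
      if (latency_window %in% c("early", "late")) {
        # < 1 below 0.5 s, > 1 above 2 s, smooth in between
        0.55 + 0.85 * (1 - short(k))
      } else {
        # both intervals matter at the intermediate stage
        1 + 0.35 * short(k) * (0.4 + 0.6 * short(k_minus_1, mid = 1.5,
                                                 slope = 0.3))
      }
    },
    diagonal = 0.55 + 0.85 * (1 - short(min(k, k_minus_1))))
}

#' Synthesize a continuous multichannel EEG recording
#'
#' Places the gain-scaled evoked template at every stimulus onset from the
#' third event onward (the first two events carry the unmodulated template,
#' as no triad is defined for them) and adds i.i.d. Gaussian noise.
#' Overlapping responses are summed linearly. The per-latency gain is
#' piecewise constant over the early (1-75 ms), intermediate (75-150 ms)
#' and late (150-300 ms) windows of [modulation_gain()].
#'
#' Channel 1 is the designated somatosensory electrode (full template);
#' other channels carry a scaled-down copy set by `channel_gains`.
#'
#' @param train a [generate_train()] object.
#' @param template an [erp_template()].
#' @param spec a [modulation_spec()].
#' @param n_channels number of channels (>= 2 so an average reference
#'   exists downstream).
#' @param channel_gains per-channel template scale; default
#'   `c(1, 0.7, 0.3, 0.3, ...)`.
#' @param noise_sd Gaussian noise SD in uV (0 gives the exact gain-scaled
#'   template at each event).
#' @param pad_ms silence appended before the first and after the last
#'   event so all epochs fit.
#' @param seed integer seed for the noise.
#' @return An `eeg_recording`: list with `data` (channels x samples, uV),
#'   `srate` (1000), `channel_labels`, `events` (the train), `meta`.
#' @export
synthesize_recording <- function(train, template, spec = modulation_spec(),
                                 n_channels = 4, channel_gains = NULL,
                                 noise_sd = 0, pad_ms = 500, seed = 1L) {
  stopifnot(inherits(train, "stim_train"), inherits(template, "erp_template"),
            length(train$onsets) >= 1, noise_sd >= 0, n_channels >= 1)
  if (is.null(channel_gains))
    channel_gains <- c(1, 0.7, rep(0.3, max(0, n_channels - 2)))[1:n_channels]
  stopifnot(length(channel_gains) == n_channels)

  onsets <- train$onsets + pad_ms            # shift so pre-event window fits
  n_samples <- max(onsets) + max(template$latencies) + 1 + pad_ms
  tmpl_len <- length(template$amplitude)
  triads <- compute_triads(train)
  win <- stage_windows()
  lat <- template$latencies
  in_win <- lapply(win, function(w) lat >= w[1] & lat <= w[2])

  base <- numeric(n_samples)
  for (i in seq_along(onsets)) {
    g <- rep(1, tmpl_len)
    if (i >= 3) {
      tr <- triads[i - 2L, ]
      for (wname in names(win)) {
        g[in_win[[wname]]] <- modulation_gain(tr$k, tr$k_minus_1, wname, spec)
      }
    }
    idx <- onsets[i] + seq_len(tmpl_len)     # sample 1 = time 0 ms
    base[idx] <- base[idx] + g * template$amplitude
  }

  data <- outer(channel_gains, base)
  if (noise_sd > 0) {
    data <- data + withr::with_seed(seed,
      matrix(stats::rnorm(n_channels * n_samples, sd = noise_sd),
             nrow = n_channels))
  }
  shifted <- train
  shifted$onsets <- onsets
  structure(list(data = data, srate = 1000,
                 channel_labels = c("SS1", "SS2",
                                    paste0("CH", seq_len(max(0, n_channels - 2))))[1:n_channels],
                 events = shifted,
                 meta = list(finger = train$finger, noise_sd = noise_sd,
                             preset = spec$preset, seed = seed,
                             channel_gains = channel_gains)),
            class = "eeg_recording")
}
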