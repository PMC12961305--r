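# a recording wrapping an arbitrary channel x sample matrix
raw_recording <- function(data, onsets = integer()) {
  structure(list(data = data, srate = 1000,
                 channel_labels = paste0("CH", seq_len(nrow(data))),
                 events = make_train(if (length(onsets)) onsets else c(0)),
                 meta = list()),
            class = "eeg_recording")
}

test_that("the band-pass filter passes the band and kills DC", {
  fs <- 1000
  t <- seq_len(20000) / fs
  sin10 <- sin(2 * pi * 10 * t)
  rec <- raw_recording(rbind(sin10, rep(100, length(t))))
  out <- bandpass(rec, 1, 45)
  mid <- 5000:15000    # away from the (already padded) edges
  amp <- max(abs(out$data[1, mid]))
  expect_gt(amp, 0.95)
  expect_lt(amp, 1.05)
  # 100 uV DC offset is outside the passband
  expect_lt(mean(abs(out$data[2, ])), 1)
  # all-zero input stays zero
  z <- bandpass(raw_recording(matrix(0, 1, 20000)), 1, 45)
  expect_true(all(z$data == 0))
  # >= 20 dB one octave into the stopbands, measured on probe sinusoids
  probes <- rbind(sin(2 * pi * 0.5 * t), sin(2 * pi * 90 * t))
  po <- bandpass(raw_recording(probes), 1, 45)
  for (i in 1:2)
    expect_lt(20 * log10(max(abs(po$data[i, mid]))), -20)
  expect_error(bandpass(raw_recording(matrix(0, 1, 20000)), 1, 600))
})

test_that("epochs align sample t=0 to the event onset", {
  n <- 5000
  dat <- matrix(0, 2, n)
  onsets <- c(50, 1000, 2500, 4900)   # first underflows, last overflows
  dat[, onsets + 1] <- 7              # impulse at each onset
  rec <- raw_recording(dat, onsets)
  ep <- epoch_events(rec)
  expect_equal(dim(ep$data), c(2, 2, 500))
  expect_identical(ep$n_dropped_edge, 2L)
  expect_identical(ep$event_index, c(2L, 3L))
  expect_identical(length(ep$time_ms), 500L)
  expect_identical(range(ep$time_ms), c(-200L, 299L))
  i0 <- which(ep$time_ms == 0)
  expect_equal(ep$data[1, 1, i0], 7)
  expect_equal(ep$data[2, 2, i0], 7)
  expect_true(all(ep$data[1, 1, -i0] == 0))
})

test_that("amplitude rejection is strict exceedance of the threshold", {
  peaks <- seq(0, 200, by = 0.5)
  dat <- array(0, dim = c(length(peaks), 1, 500))
  dat[, 1, 250] <- peaks
  ep <- reject_amplitude(make_epochs(dat))
  # boundary: exactly 80 retained, 80.5 rejected
  expect_false(ep$rejected[peaks == 80])
  expect_true(ep$rejected[peaks == 80.5])
  expect_identical(ep$rejected, peaks > 80)
  # sweep recovers the boundary operationally
  boundary <- max(peaks[!ep$rejected])
  expect_identical(boundary, 80)
  # all-zero epochs are never rejected
  ep0 <- reject_amplitude(make_epochs(array(0, dim = c(3, 2, 500))))
  expect_false(any(ep0$rejected))
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  set.seed(1)
  dat <- array(rnorm(4 * 3 * 500, mean = 5), dim = c(4, 3, 500))
  ep <- baseline_correct(make_epochs(dat))
  sel <- ep$time_ms >= -200 & ep$time_ms <= -50
  bl <- apply(ep$data[, , sel], c(1, 2), mean)
  expect_equal(max(abs(bl)), 0, tolerance = 1e-12)
  ep2 <- baseline_correct(ep)
  expect_equal(ep2$data, ep$data, tolerance = 1e-12)
  # constant epoch collapses to zero
  cst <- baseline_correct(make_epochs(array(3, dim = c(1, 1, 500))))
  expect_true(all(abs(cst$data) < 1e-12))
  expect_error(baseline_correct(make_epochs(dat), window = c(-900, -800)))
})

test_that("average reference zeroes the channel mean and is idempotent", {
  a <- sin(seq_len(500) / 10); b <- cos(seq_len(500) / 17)
  dat <- array(0, dim = c(1, 2, 500))
  dat[1, 1, ] <- a; dat[1, 2, ] <- b
  ep <- average_reference(make_epochs(dat))
  expect_equal(ep$data[1, 1, ], (a - b) / 2, tolerance = 1e-12)
  expect_equal(ep$data[1, 2, ], (b - a) / 2, tolerance = 1e-12)
  expect_equal(max(abs(apply(ep$data, c(1, 3), mean))), 0,
               tolerance = 1e-12)
  ep2 <- average_reference(ep)
  expect_equal(ep2$data, ep$data, tolerance = 1e-12)
  expect_error(average_reference(make_epochs(array(0, c(1, 1, 500)))))
})

test_that("channel selection finds the planted short-latency maximum", {
  dat <- array(0, dim = c(10, 4, 500))
  i50 <- which((-200:299) == 50)
  dat[, 1, i50] <- 3; dat[, 2, i50] <- 3; dat[, 3, i50] <- 6
  dat[, 4, i50] <- -9   # large negative must not win "max_positive"
  ep <- make_epochs(dat)
  expect_identical(as.integer(select_channel(ep, c(25, 75))), 3L)
  # max_abs criterion prefers the large negativity instead
  expect_identical(as.integer(select_channel(ep, c(25, 75),
                                             criterion = "max_abs")), 4L)
  # single-channel ROI returns that channel; ties break to lowest index
  expect_identical(as.integer(select_channel(ep, roi = 2L)), 2L)
  expect_identical(as.integer(select_channel(ep, roi = c(2L, 1L))), 1L)
  expect_error(select_channel(ep, roi = integer()))
})

test_that("the preprocessing chain preserves counts and both zero-means", {
  sub <- quick_subject(seed = 5, n_events = 200)
  ep <- sub$epochs
  expect_identical(ep$meta$pipeline_order,
                   c("filter", "epoch", "reject", "reference", "baseline"))
  # noiseless synthetic: every interior event yields a retained epoch
  expect_identical(dim(ep$data)[1] + ep$n_dropped_edge,
                   length(sub$rec$events$onsets))
  expect_false(any(ep$rejected))
  # zero baseline mean and zero channel mean hold simultaneously
  sel <- ep$time_ms >= -200 & ep$time_ms <= -50
  expect_lt(max(abs(apply(ep$data[, , sel], c(1, 2), mean))), 1e-10)
  expect_lt(max(abs(apply(ep$data, c(1, 3), mean))), 1e-10)
})
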