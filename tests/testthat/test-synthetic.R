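test_that("generated trains respect the interval range and the seed", {
  tr <- generate_train(1800, c(100, 10000), seed = 1)
  iv <- diff(tr$onsets)
  expect_length(iv, 1799)
  expect_true(all(iv >= 100 & iv <= 10000))
  expect_true(all(diff(tr$onsets) > 0))
  tr2 <- generate_train(3, seed = 42)
  tr3 <- generate_train(3, seed = 42)
  expect_identical(tr2$onsets, tr3$onsets)
  expect_error(generate_train(1800, distribution = "pareto"))
})

test_that("log-uniform intervals match their law and cover all joint bins", {
  tr <- generate_train(1800, seed = 7)
  iv <- diff(tr$onsets)
  # KS against the log-uniform CDF (rounding to 1 ms is immaterial at
  # this scale)
  ks <- suppressWarnings(stats::ks.test(
    iv, function(q) (log(q) - log(100)) / (log(10000) - log(100))))
  expect_gt(ks$p.value, 0.01)
  # analytic oracle: smallest joint-bin probability (ln2/ln100)^2, so the
  # expected count in every bin at n = 1798 triads is ~41 and each of the
  # 25 bins comfortably exceeds the 10-trial threshold
  asg <- assign_bin(compute_triads(tr), bin_grid())
  counts <- table(factor(asg$row, 1:5), factor(asg$col, 1:5))
  expect_true(all(counts >= 10))
  p_min <- (log(2) / log(100))^2
  expect_gt(min(counts), 0.3 * p_min * 1798)   # far above chance shortfall
})

test_that("the evoked template attains its configured peaks", {
  tm <- erp_template()
  # local extrema at the five configured latencies, alternating polarity
  for (i in seq_len(nrow(default_component_peaks()))) {
    lat <- default_component_peaks()$latency_ms[i]
    amp <- default_component_peaks()$amplitude_uv[i]
    win <- which(abs(tm$latencies - lat) <= 2)
    idx <- if (amp > 0) win[which.max(tm$amplitude[win])]
           else win[which.min(tm$amplitude[win])]
    expect_lte(abs(tm$latencies[idx] - lat), 2)
    expect_lt(abs(tm$amplitude[idx] - amp) / abs(amp), 0.05)
  }
  expect_identical(tm$amplitude[1], 0)
  # empty peak list gives silence; a single peak reproduces itself
  expect_true(all(erp_template(data.frame(latency_ms = numeric(),
                                          amplitude_uv = numeric()))$amplitude == 0))
  one <- erp_template(data.frame(latency_ms = 50, amplitude_uv = 5))
  expect_lte(abs(one$latencies[which.max(one$amplitude)] - 50), 2)
  expect_lt(abs(max(one$amplitude) - 5) / 5, 0.05)
  expect_error(erp_template(data.frame(latency_ms = 400,
                                       amplitude_uv = 1)))
})

test_that("modulation presets implement their gain rules", {
  none <- modulation_spec("none")
  els <- modulation_spec("early_late_suppression")
  diag <- modulation_spec("diagonal")
  expect_identical(modulation_gain(0.3, 5, "early", none), 1)
  expect_identical(modulation_gain(7, 0.2, "late", none), 1)
  # suppression below 0.5 s, enhancement above 2 s, early and late alike
  for (w in c("early", "late")) {
    expect_lt(modulation_gain(0.3, 3, w, els), 1)
    expect_lt(modulation_gain(0.49, 0.49, w, els), 1)
    expect_gt(modulation_gain(3, 0.3, w, els), 1)
    expect_gt(modulation_gain(8, 8, w, els), 1)
  }
  # diagonal preset monotone in min(k, k-1)
  g <- vapply(c(0.2, 0.5, 1, 2, 5), function(m)
    modulation_gain(m, m * 2, "early", diag), numeric(1))
  expect_true(all(diff(g) > 0))
  expect_identical(modulation_gain(1, 1, "early", diag),
                   modulation_gain(1, 8, "early", diag))
  expect_error(modulation_gain(1, 1, "ultra", els))
})

test_that("noiseless synthesis places the exact gain-scaled template", {
  tm <- erp_template()
  tr <- make_train(c(0, 400, 800, 4000, 8000))
  rec <- synthesize_recording(tr, tm, modulation_spec(), n_channels = 2,
                              noise_sd = 0)
  # epoch at every event on the somatosensory channel equals the template
  for (on in rec$events$onsets) {
    ep <- rec$data[1, on + 1 + 0:299]
    expect_equal(ep, tm$amplitude, tolerance = 1e-12)
  }
  # with suppression planted, the 50 ms peak is smaller after k = 0.3 s
  tr2 <- make_train(c(0, 3000, 3300, 10000, 13000))
  rec2 <- synthesize_recording(tr2, tm,
                               modulation_spec("early_late_suppression"),
                               n_channels = 2, noise_sd = 0)
  peak_short <- rec2$data[1, rec2$events$onsets[3] + 1 + 50]  # k = 0.3
  peak_long <- rec2$data[1, rec2$events$onsets[5] + 1 + 50]   # k = 3
  expect_lt(peak_short, peak_long)
  expect_lt(peak_short, tm$amplitude[51])
  expect_gt(peak_long, tm$amplitude[51])
  # seeded determinism of the noisy path
  ra <- synthesize_recording(tr, tm, noise_sd = 2, seed = 9)
  rb <- synthesize_recording(tr, tm, noise_sd = 2, seed = 9)
  expect_identical(ra$data, rb$data)
})

test_that("disjoint trains superpose linearly in the noiseless case", {
  # under the "none" preset every event carries gain 1, so the union of
  # two disjoint trains must synthesize to the sum of the two recordings
  tm <- erp_template()
  tr_a <- make_train(c(0, 500, 1200))
  tr_b <- make_train(c(5000, 5600, 6400))
  tr_ab <- make_train(sort(c(tr_a$onsets, tr_b$onsets)))
  synth <- function(tr) synthesize_recording(tr, tm, modulation_spec(),
                                             n_channels = 2, noise_sd = 0,
                                             pad_ms = 500)
  ra <- synth(tr_a); rb <- synth(tr_b); rab <- synth(tr_ab)
  # B's last onset is the union's last onset, so B and the union share a
  # sample axis; zero-pad A's shorter recording onto it
  expect_identical(ncol(rb$data), ncol(rab$data))
  pad_a <- cbind(ra$data,
                 matrix(0, 2, ncol(rab$data) - ncol(ra$data)))
  expect_equal(rab$data, pad_a + rb$data, tolerance = 1e-12)
})
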