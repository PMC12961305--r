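test_that("triads carry the previous and penultimate intervals", {
  tr <- make_train(c(0, 300, 900, 3000))
  td <- compute_triads(tr)
  expect_identical(td$event_index, 3:4)
  expect_equal(td$k, c(0.6, 2.1))
  expect_equal(td$k_minus_1, c(0.3, 0.6))
  expect_identical(nrow(compute_triads(make_train(c(0, 100)))), 0L)
  # n events always give n - 2 triads
  for (n in c(3L, 10L, 50L)) {
    expect_identical(nrow(compute_triads(make_train(cumsum(rep(200, n))))),
                     n - 2L)
  }
})

test_that("bin assignment is upper-bound inclusive with exclusion beyond 8 s", {
  td <- data.frame(event_index = 3:6,
                   k = c(3, 9, 0.5, 8.0001),
                   k_minus_1 = c(2.5, 1, 0.5, 1))
  asg <- assign_bin(td, bin_grid())
  expect_identical(asg$row[1], 4L)   # k-1 = 2.5 in (2, 4]
  expect_identical(asg$col[1], 4L)   # k = 3 in (2, 4]
  expect_true(is.na(asg$row[2]) && is.na(asg$col[2]))  # k = 9 excluded
  expect_identical(c(asg$row[3], asg$col[3]), c(1L, 1L))  # 0.5 in (0, 0.5]
  expect_true(is.na(asg$col[4]))    # just beyond the largest edge
  expect_error(assign_bin(data.frame(event_index = 3, k = -1,
                                     k_minus_1 = 1), bin_grid()))
})

test_that("binning matches a brute-force 2-D histogram on random triads", {
  set.seed(42)
  n <- 10000
  td <- data.frame(event_index = seq_len(n) + 2,
                   k = exp(runif(n, log(0.1), log(10))),
                   k_minus_1 = exp(runif(n, log(0.1), log(10))))
  grid <- bin_grid()
  asg <- assign_bin(td, grid)
  counts <- table(factor(asg$row, 1:5), factor(asg$col, 1:5))
  # oracle: nested-loop assignment straight from the edge definition
  edges <- c(0, grid$upper_edges)
  oracle <- matrix(0L, 5, 5)
  n_excl <- 0L
  for (i in seq_len(n)) {
    r <- c <- NA
    for (b in 1:5) {
      if (td$k_minus_1[i] > edges[b] && td$k_minus_1[i] <= edges[b + 1]) r <- b
      if (td$k[i] > edges[b] && td$k[i] <= edges[b + 1]) c <- b
    }
    if (is.na(r) || is.na(c)) n_excl <- n_excl + 1L
    else oracle[r, c] <- oracle[r, c] + 1L
  }
  expect_equal(unclass(counts), oracle, ignore_attr = TRUE)
  expect_identical(sum(is.na(asg$row)), n_excl)
})

test_that("per-bin ERPs are the brute-force means with the 10-trial rule", {
  # plant known bin memberships: 9 trials in one bin, 10 in another
  k_vals <- c(rep(0.3, 9), rep(3, 10), rep(1.5, 12))
  km1_vals <- c(rep(0.3, 9), rep(3, 10), rep(1.5, 12))
  n <- length(k_vals)
  td <- data.frame(event_index = seq_len(n) + 2, k = k_vals,
                   k_minus_1 = km1_vals)
  set.seed(7)
  dat <- array(rnorm(n * 1 * 500), dim = c(n, 1, 500))
  ep <- make_epochs(dat, event_index = seq_len(n) + 2,
                    events = make_train(cumsum(rep(200, n + 2))))
  j <- build_jierp(ep, td, channel = 1)
  expect_false(j$valid[1, 1])            # 9 trials: invalid
  expect_true(j$valid[4, 4])             # 10 trials: valid
  expect_true(j$valid[3, 3])             # 12 trials
  expect_identical(j$trial_count[1, 1], 9L)
  expect_identical(j$trial_count[4, 4], 10L)
  expect_true(all(is.na(j$amplitude[1, 1, ])))
  # brute-force averaging oracle
  expect_equal(j$amplitude[4, 4, ],
               colMeans(dat[10:19, 1, ]), tolerance = 1e-12)
  expect_equal(j$amplitude[3, 3, ],
               colMeans(dat[20:31, 1, ]), tolerance = 1e-12)
  expect_error(build_jierp(ep, td, channel = 1, min_trials = 1000))
})

test_that("trial accounting sums to the total event count", {
  sub <- quick_subject(seed = 2, n_events = 400)
  j <- build_jierp(sub$epochs, sub$triads, channel = 1)
  cnt <- j$counts
  expect_identical(cnt$first_two + cnt$excluded_over_edge +
                     cnt$unavailable_epochs + cnt$pooled,
                   cnt$total_events)
})

test_that("grand averaging follows the subject-fraction validity rule", {
  sub <- quick_subject(seed = 2, n_events = 400)
  j <- build_jierp(sub$epochs, sub$triads, channel = 1)
  # identical inputs average to themselves
  g <- grand_average(list(j, j, j))
  expect_equal(g$amplitude, j$amplitude, tolerance = 1e-12)
  expect_identical(g$valid, j$valid)
  # a bin valid in one of two subjects: kept at fraction 0.5, not at 0.8
  vb <- which(j$valid, arr.ind = TRUE)[1, ]
  j2 <- j
  j2$valid[vb[1], vb[2]] <- FALSE
  j2$amplitude[vb[1], vb[2], ] <- NA_real_
  g50 <- grand_average(list(j, j2), min_subject_fraction = 0.5)
  expect_true(g50$valid[vb[1], vb[2]])
  expect_equal(g50$amplitude[vb[1], vb[2], ], j$amplitude[vb[1], vb[2], ],
               tolerance = 1e-12)
  g80 <- grand_average(list(j, j2), min_subject_fraction = 0.8)
  expect_false(g80$valid[vb[1], vb[2]])
  # random JIERPs: per-cell mean over valid contributors
  j3 <- j
  j3$amplitude <- j$amplitude + 1
  gr <- grand_average(list(j, j3), min_subject_fraction = 0.5)
  expect_equal(gr$amplitude[j$valid & j3$valid][1],
               (j$amplitude[j$valid & j3$valid][1] +
                  j3$amplitude[j$valid & j3$valid][1]) / 2,
               tolerance = 1e-12)
  expect_error(grand_average(list()))
})

test_that("latencywise z-scores standardize the valid bins", {
  sub <- quick_subject(seed = 2, n_events = 400, noise_sd = 2)
  j <- build_jierp(sub$epochs, sub$triads, channel = 1)
  z <- zscore_latencywise(j)
  b <- j$grid$n_bins
  flat <- matrix(z$z, b * b, length(z$time_ms))[as.vector(z$valid), ]
  expect_lt(max(abs(colMeans(flat))), 1e-10)
  expect_equal(unname(apply(flat, 2, sd)),
               rep(1, ncol(flat)), tolerance = 1e-10)
  # direct oracle at one latency
  x <- j$amplitude[, , 100][j$valid]
  expect_equal(z$z[, , 100][z$valid], (x - mean(x)) / sd(x),
               tolerance = 1e-12)
  # constant latency: all-zero z, flagged
  jc <- j
  jc$amplitude[, , 1] <- 5
  zc <- zscore_latencywise(jc)
  expect_true(zc$constant_latency[1])
  expect_true(all(zc$z[, , 1][zc$valid] == 0))
  jlow <- j; jlow$valid[] <- FALSE; jlow$valid[1, 1] <- TRUE
  expect_error(zscore_latencywise(jlow))
})

test_that("planted suppression yields the short-interval z signature", {
  sub <- quick_subject(seed = 3, n_events = 600,
                       preset = "early_late_suppression")
  j <- build_jierp(sub$epochs, sub$triads,
                   channel = select_channel(sub$epochs))
  z <- zscore_latencywise(j)
  z50 <- z$z[, , which(z$time_ms == 50)]
  # every bin of the k <= 0.5 s column suppressed at the P50 latency
  expect_true(all(z50[, 1] < 0, na.rm = TRUE))
  cm <- colMeans(z50, na.rm = TRUE)
  expect_identical(which.min(cm), 1L)
})
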