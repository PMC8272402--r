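test_that("a pure periodic ensemble yields its frequency within one lag step", {
  fs <- 500
  band <- analysis_band("delta")
  for (f0 in c(1.2, 1.8, 2.5, 3.3)) {
    ens <- sine_ensemble(f0, m = 4, fs = fs, dur = 8)
    pk <- prominent_peak(aggregate_xcov(ens, band), band)
    # one reciprocal-lag grid step at f0
    lag0 <- round(fs / f0)
    df <- max(abs(1 / ((lag0 + c(-1, 1)) / fs) - f0))
    expect_lte(abs(pk$frequency - f0), df + 1e-9)
  }
})

test_that("a flat XCOV yields an absent peak, not an error", {
  lmax <- 500L
  flat <- structure(
    list(lags = (-lmax:lmax) / 500, values = rep(0, 2 * lmax + 1),
         M = 4L, n_candidate_pairs = 6L, K = 6L,
         sampling_rate = 500, band = "delta",
         subject = 1L, voxel = 1L),
    class = "xcov_result")
  pk <- prominent_peak(flat, "delta")
  expect_true(is.na(pk$frequency))
  expect_equal(nrow(pk$candidates), 0)
})

test_that("prominence ranking picks the strong component and matches brute force", {
  fs <- 500
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  sig <- sapply(1:4, function(j) {
    sin(2 * pi * 1.5 * t) + 0.35 * sin(2 * pi * 3 * t)
  })
  ens <- trial_ensemble(sig, fs, subject = 1L, voxel = 1L)
  band <- analysis_band("delta")
  xc <- aggregate_xcov(ens, band)
  pk <- prominent_peak(xc, band, n_peaks = 3)
  expect_lt(abs(pk$frequency - 1.5), 0.05)

  # brute-force prominence ranking over all in-window local maxima agrees
  # (prominence measured on the whole nonnegative-lag support)
  sup <- which(xc$lags >= 0)
  v <- xc$values[sup]
  lag_v <- xc$lags[sup]
  peaks <- brute_local_maxima(v)
  peaks <- peaks[lag_v[peaks] >= 1 / band$search_range[2] - 1e-12 &
                 lag_v[peaks] <= 1 / band$search_range[1] + 1e-12]
  prom <- vapply(peaks, function(p) brute_prominence(v, p), numeric(1))
  # the strong rhythm is prominent by a clear margin (when the weak one
  # produces a peak at all), so the ranking reduces to a plain argmax
  if (length(prom) > 1)
    expect_lt(sort(prom, decreasing = TRUE)[2] / max(prom), 0.98)
  best <- peaks[which.max(prom)]
  expect_equal(pk$frequency, 1 / lag_v[best])
  expect_equal(pk$prominence, max(prom))
})

test_that("prominence implementation agrees with the definitional scan on random series", {
  set.seed(9)
  for (rep in 1:20) {
    v <- as.numeric(stats::filter(rnorm(80), rep(1 / 5, 5), sides = 2))
    v <- v[!is.na(v)]
    peaks <- xcovpdf:::local_maxima(v)
    expect_identical(peaks, brute_local_maxima(v))
    if (length(peaks)) {
      got <- xcovpdf:::peak_prominences(v, peaks)
      want <- vapply(peaks, function(p) brute_prominence(v, p), numeric(1))
      expect_equal(got, want)
    }
  }
})

test_that("tied prominences resolve to the earliest peak", {
  # two identical triangular peaks in the search window: the earlier lag
  # (the fundamental period, were this a periodic aggregate) must win
  lmax <- 500L
  lags <- (-lmax:lmax) / 500
  v <- numeric(2 * lmax + 1)
  p1 <- lmax + 1 + 150  # lag 0.30 s -> 3.33 Hz
  p2 <- lmax + 1 + 450  # lag 0.90 s -> 1.11 Hz
  v[p1 + (-2:2)] <- c(0.2, 0.6, 1.0, 0.6, 0.2)
  v[p2 + (-2:2)] <- c(0.2, 0.6, 1.0, 0.6, 0.2)
  xc <- structure(
    list(lags = lags, values = v, M = 4L, n_candidate_pairs = 6L, K = 6L,
         sampling_rate = 500, band = "delta", subject = 1L, voxel = 1L),
    class = "xcov_result")
  pk <- prominent_peak(xc, "delta")
  expect_equal(pk$lag, 0.3)
  expect_equal(pk$frequency, 1 / 0.3)
  # a clearly more prominent late peak still wins over an early weak one
  v2 <- v
  v2[p1 + (-2:2)] <- 0.4 * v2[p1 + (-2:2)]
  xc$values <- v2
  expect_equal(prominent_peak(xc, "delta")$lag, 0.9)
})
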