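test_that("candidate pair count is M(M-1)/2", {
  expect_identical(n_candidate_pairs(38), 703)
  for (m in 2:12) {
    expect_equal(n_candidate_pairs(m), choose(m, 2))
    expect_equal(nrow(xcovpdf:::pair_indices(m)), choose(m, 2))
  }
})

test_that("zero-delay match filter accepts aligned and rejects shifted pairs", {
  fs <- 500
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  s <- sin(2 * pi * 2 * t) * (1 + 0.2 * cos(2 * pi * 0.5 * t))

  r <- zero_delay_match(s, s, tol = 0.05, sampling_rate = fs)
  expect_true(r$match)
  expect_equal(r$delay, 0)

  half_period <- 0.25
  s_shift <- sin(2 * pi * 2 * (t - half_period))
  r2 <- zero_delay_match(sin(2 * pi * 2 * t), s_shift,
                         tol = half_period / 2, sampling_rate = fs,
                         max_lag = 0.5)
  expect_false(r2$match)

  expect_error(zero_delay_match(rep(1, 100), rnorm(100), 0.05, fs),
               class = "xcovpdf_degenerate_signal")
  expect_error(zero_delay_match(rnorm(100), rnorm(99), 0.05, fs),
               class = "xcovpdf_parameter_error")
})

test_that("match filter recovers a known small delay within grid resolution", {
  fs <- 500
  true_delay <- 0.010
  set.seed(4)
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2.5 * t) + rnorm(length(t), 0, 0.2)
  y <- sin(2 * pi * 2.5 * (t - true_delay)) + rnorm(length(t), 0, 0.2)
  r <- zero_delay_match(x, y, tol = 0.05, sampling_rate = fs, max_lag = 0.3)
  expect_true(r$match)
  expect_lte(abs(abs(r$delay) - true_delay), 1 / fs)
})

test_that("aggregate equals the brute-force mean over qualifying pairs", {
  fs <- 500
  band <- analysis_band("delta")
  tol <- default_match_tol(band)
  set.seed(11)
  ens <- sine_ensemble(2.2, m = 6, fs = fs, dur = 2.5, noise_sd = 0.4,
                       delays = rnorm(6, 0, 0.01), seed = 11)
  xc <- aggregate_xcov(ens, band, tol)

  xf <- bandlimit(ens$signals, band, fs)
  lmax <- xcovpdf:::xcov_lmax(band, fs, nrow(ens$signals))
  cc_raw <- sapply(seq_len(choose(6, 2)), function(k) {
    ij <- xcovpdf:::pair_indices(6)[k, ]
    brute_xcorr(xf[, ij[1]], xf[, ij[2]], lmax)
  })
  cc_unb <- sapply(seq_len(choose(6, 2)), function(k) {
    ij <- xcovpdf:::pair_indices(6)[k, ]
    brute_xcorr(xf[, ij[1]], xf[, ij[2]], lmax, unbias = TRUE)
  })
  lags <- (-lmax:lmax) / fs
  # delay decision on the raw functions, aggregation of the corrected ones
  delays <- lags[apply(cc_raw, 2, which.max)]
  qual <- abs(delays) <= tol + 1e-12
  expect_gte(sum(qual), 1)
  expect_equal(xc$K, sum(qual))
  expect_equal(xc$values, rowMeans(cc_unb[, qual, drop = FALSE]),
               tolerance = 1e-10)
  expect_equal(xc$n_candidate_pairs, 15)
})

test_that("duplicated trials reduce XCOV to the trial autocorrelation", {
  cfg <- quick_cfg(snr_db = 40, n_trials = 1)
  tr <- make_event_train(1.8, 4, 0.15)
  x <- simulate_trial(tr, cfg, seed = 3)
  m <- 5
  ens <- trial_ensemble(matrix(rep(x, m), ncol = m), cfg$sampling_rate,
                        subject = 1L, voxel = 1L)
  band <- analysis_band("delta")
  xc <- aggregate_xcov(ens, band)
  expect_equal(xc$K, choose(m, 2))

  xf <- bandlimit(x, band, cfg$sampling_rate)
  lmax <- xcovpdf:::xcov_lmax(band, cfg$sampling_rate, length(x))
  acf_ref <- brute_xcorr(xf, xf, lmax, unbias = TRUE)
  expect_equal(xc$values, acf_ref, tolerance = 1e-10)
  # maximum at (numerically within one sample of) zero lag, like an
  # autocorrelation
  expect_lte(abs(which.max(xc$values) - (lmax + 1L)), 1L)
})

test_that("an ensemble with no zero-delay pair raises the no-pairs condition", {
  fs <- 500
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  sig <- cbind(sin(2 * pi * 2 * t), sin(2 * pi * 2 * (t - 0.25)))
  ens <- trial_ensemble(sig, fs)
  expect_error(aggregate_xcov(ens, "delta", tol = 0.0625),
               class = "xcovpdf_no_pairs")
})

test_that("XCOV values stay within the overlap-corrected correlation bound", {
  ens <- simulate_cell(quick_cfg(n_trials = 8, snr_db = 0,
                                 delay_jitter_sd = 0.02, seed = 6), 1, 1)
  xc <- aggregate_xcov(ens, "delta")
  expect_true(all(is.finite(xc$values)))
  # |c(l)| <= n/(n - lmax) after the unbiased-overlap correction
  n <- nrow(ens$signals)
  lmax <- xcovpdf:::xcov_lmax(analysis_band("delta"), ens$sampling_rate, n)
  expect_true(all(abs(xc$values) <= n / (n - lmax) + 1e-9))
  expect_true(xc$K >= 1 && xc$K <= xc$n_candidate_pairs)
})
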