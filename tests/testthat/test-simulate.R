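test_that("trial simulation is deterministic given a seed", {
  cfg <- quick_cfg(n_trials = 2)
  tr <- make_event_train(1.8, 4, 0.15)
  x1 <- simulate_trial(tr, cfg, seed = 77)
  x2 <- simulate_trial(tr, cfg, seed = 77)
  expect_identical(x1, x2)
  x3 <- simulate_trial(tr, cfg, seed = 78)
  expect_false(identical(x1, x3))
  expect_length(x1, round(cfg$duration * cfg$sampling_rate))
  expect_true(all(is.finite(x1)))
})

test_that("noiseless construction puts the sub-6-Hz spectral maximum at the chunk rate", {
  for (rate in c(1.8, 2.6)) {
    cfg <- quick_cfg(chunk_rate = rate, duration = 10, snr_db = 60,
                     delay_jitter_sd = 0)
    tr <- make_event_train(rate, floor(10 * rate), cfg$digit_offset)
    x <- simulate_trial(tr, cfg, seed = 5)
    n <- length(x)
    f <- (0:(n - 1)) * cfg$sampling_rate / n
    p <- Mod(fft(x))^2
    sub <- f > 0.3 & f < 6
    f_peak <- f[sub][which.max(p[sub])]
    expect_lt(abs(f_peak - rate), cfg$sampling_rate / n + 1e-9)
  }
})

test_that("at very low SNR two trials from the same train are uncorrelated", {
  cfg <- quick_cfg(snr_db = -60, duration = 4)
  tr <- make_event_train(1.8, 7, 0.15)
  x <- simulate_trial(tr, cfg, seed = 1)
  y <- simulate_trial(tr, cfg, seed = 2)
  expect_gte(length(x), 1000)
  expect_lt(abs(cor(x, y)), 0.1)
})

test_that("snr_db sets the 0.5-10 Hz signal-to-noise variance ratio", {
  tr <- make_event_train(1.8, 4, 0.15)
  fs <- 500
  # same seed -> identical signal component and noise draw; only the noise
  # scale changes with snr_db, so the difference isolates the noise term
  clean <- simulate_trial(tr, quick_cfg(snr_db = 200, delay_jitter_sd = 0),
                          seed = 9)
  for (snr in c(10, 0, -10)) {
    noisy <- simulate_trial(tr, quick_cfg(snr_db = snr, delay_jitter_sd = 0),
                            seed = 9)
    bv <- unname(xcovpdf:::band_variance(cbind(clean, noisy - clean), fs))
    expect_equal(10 * log10(bv[1] / bv[2]), snr, tolerance = 0.01)
  }
})

test_that("dataset simulation has the right cell structure and is reproducible", {
  cfg <- quick_cfg(n_voxels = 2, n_subjects = 3, n_trials = 4, snr_db = 0,
                   seed = 21)
  ds1 <- simulate_dataset(cfg)
  expect_s3_class(ds1, "source_dataset")
  expect_length(ds1$cells, 6)
  expect_true(all(vapply(ds1$cells, function(c) ncol(c$signals), 0L) == 4))
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$cells, ds2$cells)

  # per-cell reproducibility without simulating the rest
  cell <- simulate_cell(cfg, subject = 2, voxel = 2)
  expect_identical(cell$signals, ds1$cells[["s02_v02"]]$signals)

  # different seeds give different data
  ds3 <- simulate_dataset(quick_cfg(n_voxels = 2, n_subjects = 3,
                                    n_trials = 4, snr_db = 0, seed = 22))
  expect_false(identical(ds1$cells[[1]]$signals, ds3$cells[[1]]$signals))
})

test_that("behavior simulation respects the binomial partition", {
  b <- simulate_behavior(1.0, 0.0, 50, 50, seed = 1)
  expect_equal(b$n_hit, 50)
  expect_equal(b$n_miss, 0)
  expect_equal(b$n_fa, 0)
  expect_equal(b$n_cr, 50)

  for (s in 1:5) {
    b <- simulate_behavior(0.7, 0.3, 40, 25, seed = s)
    expect_equal(b$n_hit + b$n_miss, 40)
    expect_equal(b$n_fa + b$n_cr, 25)
  }

  big <- simulate_behavior(0.8, 0.2, 10000, 10000, seed = 3)
  expect_lt(abs(big$n_hit / 10000 - 0.8), 0.02)
  expect_lt(abs(big$n_fa / 10000 - 0.2), 0.02)

  expect_identical(simulate_behavior(0.6, 0.2, 30, 30, seed = 4),
                   simulate_behavior(0.6, 0.2, 30, 30, seed = 4))
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(sampling_rate = 15),
               class = "xcovpdf_parameter_error")
  expect_error(synth_config(chunk_rate = 1.8, duration = 0.5),
               class = "xcovpdf_parameter_error")
  expect_error(synth_config(n_trials = 0), class = "xcovpdf_parameter_error")
  expect_error(synth_config(digit_offset = 0.9, chunk_rate = 1.8),
               class = "xcovpdf_parameter_error")
  expect_error(simulate_behavior(1.2, 0, 10, 10),
               class = "xcovpdf_parameter_error")
})
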