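test_that("collect_peaks gives one row per cell and matches a per-cell recount", {
  cfg <- quick_cfg(n_voxels = 2, n_subjects = 2, n_trials = 5, snr_db = 10,
                   delay_jitter_sd = 0.01, seed = 14)
  ds <- simulate_dataset(cfg)
  band <- analysis_band("delta")
  pk <- collect_peaks(ds, band)
  expect_equal(nrow(pk), 4)
  expect_setequal(paste(pk$subject, pk$voxel), paste(ds$cells |>
    vapply(function(c) c$subject, 0L), ds$cells |> vapply(function(c) c$voxel, 0L)))

  # brute recount per cell
  for (r in seq_len(nrow(pk))) {
    cell <- ds$cells[[sprintf("s%02d_v%02d", pk$subject[r], pk$voxel[r])]]
    xc <- tryCatch(aggregate_xcov(cell, band), xcovpdf_no_pairs = function(e) NULL)
    if (is.null(xc)) {
      expect_true(is.na(pk$frequency[r]))
      expect_equal(pk$K[r], 0L)
    } else {
      expect_equal(pk$frequency[r], prominent_peak(xc, band)$frequency)
      expect_equal(pk$K[r], xc$K)
    }
  }
})

test_that("cells of pure noise lower the in-range count exactly as recounted", {
  band <- analysis_band("delta")
  # half the cells carry a clean 1.8 Hz signal, half are flat-spectrum noise
  set.seed(31)
  fs <- 500
  t <- seq(0, 2.38 - 1 / fs, by = 1 / fs)
  mk <- function(noisy) {
    sig <- sapply(1:4, function(j) {
      if (noisy) rnorm(length(t))
      else sin(2 * pi * 1.8 * t) + rnorm(length(t), 0, 0.05)
    })
    trial_ensemble(sig, fs, subject = 1L, voxel = 1L)
  }
  cells <- c(lapply(1:3, function(i) mk(FALSE)), lapply(1:3, function(i) mk(TRUE)))
  for (i in seq_along(cells)) { cells[[i]]$subject <- i; cells[[i]]$voxel <- 1L }
  names(cells) <- sprintf("s%02d_v01", 1:6)
  ds <- structure(list(cells = cells, n_subjects = 6L, n_voxels = 1L,
                       config = quick_cfg(n_subjects = 6, n_trials = 4)),
                  class = "source_dataset")
  pk <- collect_peaks(ds, band)
  recount <- sum(vapply(cells, function(cell) {
    xc <- tryCatch(aggregate_xcov(cell, band), xcovpdf_no_pairs = function(e) NULL)
    if (is.null(xc)) return(FALSE)
    f <- prominent_peak(xc, band)$frequency
    isTRUE(f >= 1 && f <= 4)
  }, logical(1)))
  h <- build_histogram(pk, band)
  expect_equal(h$n_in_range, recount)
})

test_that("histogram occupancy fractions follow the in-range counts", {
  band <- analysis_band("delta")
  all_in <- rep(c(1.7, 1.8, 1.9), length.out = 380)
  h1 <- build_histogram(all_in, band, scale_total = 380)
  expect_equal(h1$P, 1.0)
  expect_equal(sum(h1$counts), 380)

  h0 <- build_histogram(rep(NA_real_, 380), band, scale_total = 380)
  expect_equal(h0$P, 0)
  expect_true(all(h0$counts == 0))

  half <- c(rep(1.8, 190), rep(NA_real_, 190))
  h2 <- build_histogram(half, band, scale_total = 380)
  expect_equal(h2$P, 0.5)

  # P is a count ratio, invariant to bin width
  for (bw in c(0.05, 0.1, 0.25, 0.4)) {
    hb <- build_histogram(half, band, bin_width = bw, scale_total = 380)
    expect_equal(hb$P, 0.5)
    expect_equal(sum(hb$counts), 190)
  }
  # out-of-range peaks are recorded but not counted
  h3 <- build_histogram(c(rep(1.8, 100), rep(5.5, 280)), band,
                        scale_total = 380)
  expect_equal(h3$n_in_range, 100)
})

test_that("GMM recovers a concentrated periodicity density", {
  set.seed(2)
  f <- rnorm(380, 1.8, 0.05)
  fit <- fit_gmm(f, scale_total = 380)
  expect_true(fit$converged)
  expect_lt(abs(fit$prominent_mu - 1.8), 0.02)
  expect_lte(fit$prominent_sigma, 0.07)
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-6)
  expect_true(all(fit$components$sd > 0))
  expect_equal(fit$P, 1.0)
})

test_that("GMM recovers three separated components (best permutation)", {
  set.seed(7)
  truth <- c(1.5, 2.5, 3.4)
  f <- c(rnorm(266, truth[1], 0.05), rnorm(76, truth[2], 0.07),
         rnorm(38, truth[3], 0.06))
  fit <- fit_gmm(f, scale_total = 380)
  expect_true(fit$converged)
  got <- sort(fit$components$mean)
  expect_true(all(abs(got - truth) <= 0.05))
  # prominent component is the heaviest one
  expect_equal(fit$prominent_mu,
               fit$components$mean[which.max(fit$components$weight)])
})

test_that("insufficient samples yield a non-converged PDF, never an error", {
  fit <- fit_gmm(c(1.8, 1.9), scale_total = 380)
  expect_false(fit$converged)
  expect_true(is.na(fit$prominent_mu))
  expect_true(is.na(fit$prominent_sigma))
  expect_equal(fit$P, 2 / 380)
  g <- goodness(fit, 1.8)
  expect_true(is.na(g$bias))
  expect_equal(g$P, 2 / 380)
})

test_that("goodness and its ROI summary follow the definitions", {
  p1 <- periodicity_pdf(1, 1.8, 0.1, P = 0.6)
  expect_equal(goodness(p1, 1.8)$bias, 0)
  p2 <- periodicity_pdf(1, 2.0, 0.1, P = 0.8)
  expect_equal(goodness(p2, 1.8)$bias, 0.2)

  gl <- list(list(P = 0.6, bias = 0.1), list(P = 0.8, bias = 0.3))
  s <- summarize_goodness(gl)
  expect_equal(s$bias_mean, 0.2)
  expect_equal(s$bias_var, var(c(0.1, 0.3)))
  expect_equal(s$P_mean, 0.7)
})

test_that("grid KLD matches the closed-form Gaussian divergence", {
  # parameter draws keep both densities above the 1e-12 floor across the
  # whole grid, where the floored/renormalized grid sum is a faithful
  # estimate of the analytic divergence
  set.seed(5)
  for (i in 1:20) {
    mu <- runif(2, 2.3, 2.7)
    sdv <- runif(2, 0.25, 0.4)
    p <- periodicity_pdf(1, mu[1], sdv[1])
    q <- periodicity_pdf(1, mu[2], sdv[2])
    analytic <- log(sdv[2] / sdv[1]) +
      (sdv[1]^2 + (mu[1] - mu[2])^2) / (2 * sdv[2]^2) - 0.5
    got <- kld(p, q)$kld
    expect_lt(abs(got - analytic), max(0.02 * analytic, 1e-4))
  }
})

test_that("KLD identity, nonnegativity, and the frequency-shift semantics", {
  p <- periodicity_pdf(c(0.6, 0.3, 0.1), c(1.6, 2.0, 2.8), c(0.1, 0.2, 0.15))
  expect_equal(kld(p, p)$kld, 0)

  set.seed(12)
  for (i in 1:10) {
    a <- periodicity_pdf(prop.table(runif(3)), runif(3, 1.3, 3.5),
                         runif(3, 0.05, 0.3))
    b <- periodicity_pdf(prop.table(runif(3)), runif(3, 1.3, 3.5),
                         runif(3, 0.05, 0.3))
    expect_gte(kld(a, b)$kld, 0)
  }

  # q centered 0.8 Hz above p: aligned after shift, divergent without
  p18 <- periodicity_pdf(1, 1.8, 0.12)
  p26 <- periodicity_pdf(1, 2.6, 0.12)
  shifted <- kld(p26, p18, shift = -0.8)$kld
  unshifted <- kld(p26, p18, shift = 0)$kld
  expect_lt(shifted, 0.01)
  expect_gt(unshifted, 1)

  nc <- fit_gmm(numeric(0))
  expect_error(kld(nc, p18), class = "xcovpdf_comparison_undefined")
  expect_error(pdf_density(nc, 1:3), class = "xcovpdf_comparison_undefined")
})
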