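# Independent oracles and small fixtures, kept deliberately naive.

# Energy-normalized cross-correlation by direct summation:
# c(l) = sum_t x[t+l] y[t] / sqrt(sum x^2 sum y^2), l = -lmax..lmax.
# With unbias = TRUE the finite-overlap taper is undone by n/(n-|l|).
brute_xcorr <- function(x, y, lmax, unbias = FALSE) {
  n <- length(x)
  denom <- sqrt(sum(x^2) * sum(y^2))
  vapply(-lmax:lmax, function(l) {
    if (l >= 0) s <- sum(x[(1 + l):n] * y[1:(n - l)])
    else s <- sum(x[1:(n + l)] * y[(1 - l):n])
    out <- s / denom
    if (unbias) out <- out * n / (n - abs(l))
    out
  }, numeric(1))
}

# Topographic prominence by definition, scanning every index explicitly.
brute_prominence <- function(v, p) {
  h <- v[p]
  left_stop <- 0L
  for (i in seq(p - 1, 1)) if (v[i] > h) { left_stop <- i; break }
  base_l <- min(v[seq(max(left_stop, 1L), p)])
  right_stop <- length(v) + 1L
  for (i in seq(p + 1, length(v))) if (v[i] > h) { right_stop <- i; break }
  base_r <- min(v[seq(p, min(right_stop, length(v)))])
  h - max(base_l, base_r)
}

# All strict local maxima of a vector, by definition.
brute_local_maxima <- function(v) {
  out <- integer(0)
  for (i in seq(2, length(v) - 1))
    if (v[i] > v[i - 1] && v[i] > v[i + 1]) out <- c(out, i)
  out
}

# Small generator config for fast unit tests.
quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(chunk_rate = 1.8, n_voxels = 1, n_subjects = 1,
                   n_trials = 6, snr_db = 20, delay_jitter_sd = 0,
                   phase_jitter_sd = 0, seed = 1L)
  do.call(synth_config, utils::modifyList(defaults, args))
}

# Ensemble of noiseless periodic trials at frequency f0 (sinusoid-based;
# independent of the package's own generator).
sine_ensemble <- function(f0, m = 4, fs = 500, dur = 3, noise_sd = 0,
                          delays = rep(0, m), seed = 1) {
  set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sig <- sapply(seq_len(m), function(j) {
    sin(2 * pi * f0 * (t - delays[j])) + rnorm(length(t), 0, noise_sd)
  })
  trial_ensemble(sig, fs, subject = 1L, voxel = 1L)
}
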