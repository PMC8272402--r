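# Synthetic source-signal generator.
#
# Each trial is built as: (event train convolved with a smooth unimodal
# response kernel) + theta_amplitude_ratio * (digit train convolved with the
# same kernel) + 1/f^chi Gaussian noise scaled to the requested SNR in the
# 0.5-10 Hz band, the whole trial circularly shifted by a Normal(0,
# delay_jitter_sd) delay. Per-event timing is perturbed by phase jitter.
# All randomness is driven by per-trial seeds derived from the master seed,
# so any dataset, cell or single trial is reproducible in isolation.

# Gamma-shaped evoked-like response kernel (shape 2, scale 40 ms), peak 1.
response_kernel <- function(sampling_rate, shape = 2, scale = 0.04,
                            length_s = 0.4) {
  tk <- seq(0, length_s, by = 1 / sampling_rate)
  k <- dgamma(tk, shape = shape, scale = scale)
  k / max(k)
}

# Per-column variance restricted to a frequency band, via the periodogram.
band_variance <- function(x, sampling_rate, band = c(0.5, 10)) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- Mod(mvfft(x))^2 / n^2
  f_eff <- pmin(0:(n - 1), n - (0:(n - 1))) * sampling_rate / n
  sel <- f_eff >= band[1] & f_eff <= band[2]
  colSums(p[sel, , drop = FALSE])
}

# Impulse vector of length n with unit mass at each event time (s).
impulse_train <- function(times, n, sampling_rate) {
  idx <- round(times * sampling_rate) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  v <- numeric(n)
  for (i in idx) v[i] <- v[i] + 1
  v
}

# Simulate all trials of one cell; seeds has one entry per trial.
# FFT work is batched across trials; the per-trial random draws depend only
# on that trial's seed, so column j equals simulate_trial(train, cfg,
# seeds[j]) exactly.
simulate_cell_signals <- function(train, cfg, seeds) {
  fs <- cfg$sampling_rate
  n <- round(cfg$duration * fs)
  m <- length(seeds)
  n_ch <- length(train$chunk_onsets)
  n_dg <- length(train$digit_onsets)
  digit_rate <- 2 * train$chunk_rate

  kern <- response_kernel(fs)
  nc <- stats::nextn(n + length(kern) - 1L, 2)
  fk <- fft(c(kern, numeric(nc - length(kern))))

  imp <- matrix(0, nc, m)
  white <- matrix(0, n, m)
  delay_smp <- integer(m)
  for (j in seq_len(m)) {
    draws <- with_seed(seeds[j], {
      list(jc = rnorm(n_ch), jd = rnorm(n_dg), w = rnorm(n), d = rnorm(1))
    })
    # phase jitter in radians -> seconds at the component's own rate
    t_ch <- train$chunk_onsets +
      draws$jc * cfg$phase_jitter_sd / (2 * pi * train$chunk_rate)
    t_dg <- train$digit_onsets +
      draws$jd * cfg$phase_jitter_sd / (2 * pi * digit_rate)
    imp[seq_len(n), j] <- impulse_train(t_ch, n, fs) +
      cfg$theta_amplitude_ratio * impulse_train(t_dg, n, fs)
    white[, j] <- draws$w
    delay_smp[j] <- as.integer(round(draws$d * cfg$delay_jitter_sd * fs))
  }

  sig <- Re(mvfft(mvfft(imp) * fk, inverse = TRUE))[seq_len(n), , drop = FALSE] / nc

  # spectrally shaped background noise
  f_eff <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  shape_amp <- ifelse(f_eff > 0, f_eff^(-cfg$noise_exponent / 2), 0)
  noise <- Re(mvfft(mvfft(white) * shape_amp, inverse = TRUE)) / n

  # scale noise so band-limited variance ratio matches snr_db
  snr_lin <- 10^(cfg$snr_db / 10)
  bv_sig <- band_variance(sig, fs)
  bv_noise <- band_variance(noise, fs)
  sc <- ifelse(bv_sig > 0 & bv_noise > 0,
               sqrt(bv_sig / (bv_noise * snr_lin)), 1)
  x <- sig + noise * rep(sc, each = n)

  # circular delay shift, per trial
  for (j in seq_len(m)) {
    s <- delay_smp[j] %% n
    if (s != 0) x[, j] <- x[c((n - s + 1L):n, 1L:(n - s)), j]
  }
  x
}

#' Simulate one trial of a chunk-locked neural signal
#'
#' @param train An [make_event_train()] event train; must fit within
#'   `cfg$duration`.
#' @param cfg A [synth_config()].
#' @param seed Integer seed for this trial's random draws; the same seed
#'   always yields the same series.
#' @return Numeric vector of `round(cfg$duration * cfg$sampling_rate)`
#'   samples.
#' @examples
#' cfg <- synth_config(n_voxels = 1, n_subjects = 1, n_trials = 1)
#' tr <- make_event_train(1.8, 4, 0.15)
#' x <- simulate_trial(tr, cfg, seed = 42)
#' @export
simulate_trial <- function(train, cfg, seed) {
  stopifnot(inherits(train, "event_train"), inherits(cfg, "synth_config"))
  if (train$duration > cfg$duration + 1e-9)
    stop_xcovpdf("event train exceeds the configured epoch duration",
                 "xcovpdf_parameter_error")
  simulate_cell_signals(train, cfg, as.integer(seed))[, 1]
}

# Event train implied by a config: as many whole chunks as fit the epoch.
config_train <- function(cfg) {
  n_chunks <- max(1L, floor(cfg$duration * cfg$chunk_rate + 1e-9))
  make_event_train(cfg$chunk_rate, n_chunks, cfg$digit_offset)
}

cell_seed_matrix <- function(cfg) {
  matrix(derive_seeds(cfg$seed, cfg$n_subjects * cfg$n_voxels),
         nrow = cfg$n_subjects, ncol = cfg$n_voxels)
}

#' Simulate a full (subject x voxel) source dataset
#'
#' Generates the L x N grid of trial ensembles for one ROI-like dataset:
#' every cell holds M trials driven by the same stimulus event train, with
#' independent noise and jitter. Cell substreams are derived from
#' `cfg$seed`, so [simulate_cell()] reproduces any single cell without
#' generating the rest.
#'
#' @param cfg A [synth_config()].
#' @param condition,response_class Optional labels stored with the dataset.
#' @param roi_name Optional ROI label.
#' @return An object of class `source_dataset`: list with `cells` (named
#'   list of [trial_ensemble()]s, subjects varying fastest), `n_subjects`,
#'   `n_voxels`, `train`, `config`, and the labels.
#' @examples
#' ds <- simulate_dataset(synth_config(n_voxels = 2, n_subjects = 3,
#'                                     n_trials = 4, seed = 1))
#' length(ds$cells)  # 6
#' @export
simulate_dataset <- function(cfg, condition = sprintf("%g Hz", cfg$chunk_rate),
                             response_class = NA_character_,
                             roi_name = NA_character_) {
  stopifnot(inherits(cfg, "synth_config"))
  train <- config_train(cfg)
  seeds <- cell_seed_matrix(cfg)
  cells <- vector("list", cfg$n_subjects * cfg$n_voxels)
  nm <- character(length(cells))
  k <- 0L
  for (j in seq_len(cfg$n_voxels)) {
    for (i in seq_len(cfg$n_subjects)) {
      k <- k + 1L
      trial_seeds <- derive_seeds(seeds[i, j], cfg$n_trials)
      cells[[k]] <- trial_ensemble(
        simulate_cell_signals(train, cfg, trial_seeds),
        cfg$sampling_rate, subject = i, voxel = j,
        condition = condition, response_class = response_class)
      nm[k] <- sprintf("s%02d_v%02d", i, j)
    }
  }
  names(cells) <- nm
  structure(
    list(cells = cells, n_subjects = cfg$n_subjects, n_voxels = cfg$n_voxels,
         train = train, config = cfg, condition = condition,
         response_class = response_class, roi_name = roi_name),
    class = "source_dataset"
  )
}

#' Regenerate a single cell of a dataset
#'
#' Reproduces the trial ensemble that [simulate_dataset()] would place at
#' `(subject, voxel)`, without simulating any other cell.
#'
#' @param cfg A [synth_config()].
#' @param subject,voxel Cell indices (1-based).
#' @return A [trial_ensemble()].
#' @export
simulate_cell <- function(cfg, subject, voxel) {
  stopifnot(inherits(cfg, "synth_config"),
            subject >= 1, subject <= cfg$n_subjects,
            voxel >= 1, voxel <= cfg$n_voxels)
  train <- config_train(cfg)
  seeds <- cell_seed_matrix(cfg)
  trial_seeds <- derive_seeds(seeds[subject, voxel], cfg$n_trials)
  trial_ensemble(simulate_cell_signals(train, cfg, trial_seeds),
                 cfg$sampling_rate, subject = as.integer(subject),
                 voxel = as.integer(voxel))
}

#' Simulate yes-no behavioral outcomes
#'
#' Draws hit and false-alarm counts from independent binomials, mirroring a
#' target identification task with target-present and target-absent trials.
#'
#' @param p_hit,p_fa Per-trial probabilities of a "yes" response on
#'   target-present and target-absent trials.
#' @param n_present,n_absent Trial counts per class (>= 1).
#' @param seed Optional integer seed.
#' @return A [behavioral_counts()] object (misses and correct rejections are
#'   the complements).
#' @examples
#' simulate_behavior(0.85, 0.15, 50, 50, seed = 3)
#' @export
simulate_behavior <- function(p_hit, p_fa, n_present, n_absent, seed = NULL) {
  if (any(c(p_hit, p_fa) < 0) || any(c(p_hit, p_fa) > 1))
    stop_xcovpdf("probabilities must lie in [0, 1]", "xcovpdf_parameter_error")
  if (n_present < 1 || n_absent < 1)
    stop_xcovpdf("trial counts must be >= 1", "xcovpdf_parameter_error")
  draw <- function() {
    hits <- rbinom(1, n_present, p_hit)
    fa <- rbinom(1, n_absent, p_fa)
    behavioral_counts(n_hit = hits, n_miss = n_present - hits,
                      n_fa = fa, n_cr = n_absent - fa)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
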