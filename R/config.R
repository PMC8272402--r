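#' Configuration for the synthetic source-signal generator
#'
#' Bundles and validates every parameter of the generator. Defaults follow the
#' study conditions the pipeline is designed for: 19 subjects, 20 voxels per
#' ROI, ~30 usable trials per cell, signals down-sampled to 500 Hz and epoched
#' to the minimum stimulus duration of the condition (2.38 s for the 1.8-Hz
#' chunk rate, 1.68 s for 2.6 Hz).
#'
#' @param chunk_rate Chunk presentation rate in Hz (1.8 or 2.6 in the study).
#' @param n_subjects,n_voxels,n_trials Ensemble dimensions N, L, M (>= 1).
#' @param sampling_rate Sampling rate in Hz; must exceed twice the highest
#'   analysis frequency (10 Hz).
#' @param duration Epoch length in seconds (>= two chunk periods). `NULL`
#'   selects the condition default: the study epoch lengths 2.38 s at
#'   1.8 Hz and 1.68 s at 2.6 Hz (both spanning ~4.3 chunk cycles), and
#'   `4.3 / chunk_rate` for any other rate so the cycle count per epoch
#'   stays comparable.
#' @param snr_db Signal-to-noise ratio in dB, defined as the ratio of the
#'   event-locked signal variance to the background-noise variance within the
#'   0.5-10 Hz band.
#' @param delay_jitter_sd SD (s) of the whole-trial delay, applied as a
#'   circular shift; models trial-to-trial response latency variability.
#' @param phase_jitter_sd SD (radians, relative to the chunk cycle) of
#'   per-event timing perturbations; models within-trial irregularity.
#' @param noise_exponent Spectral exponent chi of the 1/f^chi background.
#' @param theta_amplitude_ratio Amplitude of the digit-locked (theta-rate)
#'   component relative to the chunk-locked component.
#' @param digit_offset Within-chunk onset delay of the second digit (s).
#' @param seed Integer master seed; every cell and trial derives a
#'   reproducible substream from it.
#' @return An object of class `synth_config` (a validated named list).
#' @examples
#' cfg <- synth_config(chunk_rate = 1.8, n_voxels = 2, n_subjects = 2,
#'                     n_trials = 4, seed = 7)
#' cfg$duration
#' @export
synth_config <- function(chunk_rate = 1.8,
                         n_subjects = 19,
                         n_voxels = 20,
                         n_trials = 30,
                         sampling_rate = 500,
                         duration = NULL,
                         snr_db = 0,
                         delay_jitter_sd = 0.02,
                         phase_jitter_sd = 0,
                         noise_exponent = 1,
                         theta_amplitude_ratio = 0.5,
                         digit_offset = 0.15,
                         seed = 1L) {
  if (is.null(duration)) {
    duration <- if (abs(chunk_rate - 1.8) < 0.05) 2.38
                else if (abs(chunk_rate - 2.6) < 0.05) 1.68
                else round(4.3 / chunk_rate, 2)
  }
  cfg <- list(chunk_rate = chunk_rate, n_subjects = as.integer(n_subjects),
              n_voxels = as.integer(n_voxels), n_trials = as.integer(n_trials),
              sampling_rate = sampling_rate, duration = duration,
              snr_db = snr_db, delay_jitter_sd = delay_jitter_sd,
              phase_jitter_sd = phase_jitter_sd,
              noise_exponent = noise_exponent,
              theta_amplitude_ratio = theta_amplitude_ratio,
              digit_offset = digit_offset, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_xcovpdf(msg, "xcovpdf_parameter_error")
  chk(cfg$chunk_rate > 0, "chunk_rate must be positive")
  chk(cfg$n_subjects >= 1L && cfg$n_voxels >= 1L && cfg$n_trials >= 1L,
      "n_subjects, n_voxels and n_trials must all be >= 1")
  # 10 Hz is the highest frequency any analysis band passes
  chk(cfg$sampling_rate > 2 * 10,
      "sampling_rate must exceed twice the highest analysis frequency (10 Hz)")
  chk(cfg$duration >= 2 / cfg$chunk_rate,
      "duration must cover at least two chunk periods")
  chk(cfg$digit_offset > 0 && cfg$digit_offset < 1 / cfg$chunk_rate,
      "digit_offset must lie strictly inside one chunk period")
  chk(cfg$delay_jitter_sd >= 0 && cfg$phase_jitter_sd >= 0,
      "jitter SDs must be nonnegative")
  chk(cfg$theta_amplitude_ratio >= 0, "theta_amplitude_ratio must be >= 0")
  chk(is.finite(cfg$snr_db), "snr_db must be finite")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    paste0("<synth_config> %g Hz chunks, L=%d voxels x N=%d subjects x ",
           "M=%d trials\n  fs=%g Hz, %.2f s epochs, SNR %g dB, ",
           "delay jitter %g ms, phase jitter %g rad, seed %d\n"),
    x$chunk_rate, x$n_voxels, x$n_subjects, x$n_trials, x$sampling_rate,
    x$duration, x$snr_db, 1000 * x$delay_jitter_sd, x$phase_jitter_sd,
    x$seed))
  invisible(x)
}

#' Trial ensemble constructor
#'
#' One cell of a source dataset: the M trials recorded at one (subject, voxel)
#' for a given condition and response class, as a samples x trials matrix.
#'
#' @param signals Numeric matrix, samples in rows, trials in columns; all
#'   values finite.
#' @param sampling_rate Sampling rate in Hz.
#' @param subject,voxel Integer ids.
#' @param condition,response_class Optional labels.
#' @return An object of class `trial_ensemble`.
#' @export
trial_ensemble <- function(signals, sampling_rate, subject = NA_integer_,
                           voxel = NA_integer_, condition = NA_character_,
                           response_class = NA_character_) {
  signals <- as.matrix(signals)
  if (!all(is.finite(signals)))
    stop_xcovpdf("trial signals must be finite", "xcovpdf_parameter_error")
  structure(
    list(signals = signals, sampling_rate = sampling_rate,
         subject = subject, voxel = voxel, condition = condition,
         response_class = response_class),
    class = "trial_ensemble"
  )
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("<trial_ensemble> %d trials x %d samples @ %g Hz (s%s, v%s)\n",
              ncol(x$signals), nrow(x$signals), x$sampling_rate,
              x$subject, x$voxel))
  invisible(x)
}

#' @export
print.source_dataset <- function(x, ...) {
  cat(sprintf(
    "<source_dataset> %d voxels x %d subjects (%d cells), M=%d trials @ %g Hz\n",
    x$n_voxels, x$n_subjects, length(x$cells), x$config$n_trials,
    x$config$sampling_rate))
  invisible(x)
}
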