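# The XCOV aggregated cross-correlation measure.
#
# With M trials there are M(M-1)/2 unordered trial pairs, an order of
# magnitude more cross-correlation functions than trials. Unlike an
# autocorrelation, a pairwise cross-correlation peaks at the delay between
# the two trials, not at zero; so each candidate pair is screened by a
# zero-delay match filter, and only pairs whose cross-correlation peaks at
# (approximately) zero lag are aggregated. The aggregate then behaves like an
# autocorrelation: peak at zero, earliest nontrivial peak at the period.

# Lag half-window (samples) for the XCOV computation: one period of the
# slowest sought rhythm plus a 25% margin, so a peak exactly at 1/f_min is
# an interior local maximum, clamped to the available overlap.
xcov_lmax <- function(band, sampling_rate, n) {
  min(n - 1L, round(1.25 * sampling_rate / band$search_range[1]))
}

# Unordered pair indices in the same order cpp_pairwise_xcov emits columns.
pair_indices <- function(m) {
  i <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
  j <- unlist(lapply(seq_len(m - 1L), function(k) (k + 1L):m))
  cbind(i = i, j = j)
}

#' Number of candidate trial pairs
#'
#' @param m Trial count (>= 2).
#' @return `m * (m - 1) / 2`, e.g. 703 for `m = 38`.
#' @export
n_candidate_pairs <- function(m) {
  stopifnot(m >= 2)
  m * (m - 1) / 2
}

#' Zero-delay match filter for a trial pair
#'
#' Decides whether two equal-length signals are (approximately) delay-free:
#' their energy-normalized cross-correlation must attain its maximum within
#' `tol` seconds of zero lag. Such a pair's cross-correlation behaves like an
#' autocorrelation, qualifying it for aggregation.
#'
#' @param x,y Equal-length numeric vectors with nonzero variance.
#' @param tol Delay tolerance in seconds (> 0).
#' @param sampling_rate Sampling rate in Hz.
#' @param max_lag Lag search half-window in seconds; defaults to the full
#'   overlap (length - 1 samples).
#' @return List with `match` (logical) and `delay` (the argmax lag in
#'   seconds, returned either way).
#' @examples
#' fs <- 200; t <- seq(0, 2, by = 1/fs)
#' s <- sin(2 * pi * 2 * t)
#' zero_delay_match(s, s, tol = 0.05, sampling_rate = fs)$match  # TRUE
#' @export
zero_delay_match <- function(x, y, tol, sampling_rate, max_lag = NULL) {
  if (length(x) != length(y))
    stop_xcovpdf("signals must have equal length", "xcovpdf_parameter_error")
  if (tol <= 0)
    stop_xcovpdf("`tol` must be positive", "xcovpdf_parameter_error")
  if (var(x) == 0 || var(y) == 0)
    stop_xcovpdf("zero-variance signal in match filter",
                 "xcovpdf_degenerate_signal")
  n <- length(x)
  lmax <- if (is.null(max_lag)) n - 1L
          else min(n - 1L, max(1L, round(max_lag * sampling_rate)))
  res <- cpp_pairwise_xcov(cbind(x, y), as.integer(lmax))
  lags <- (-lmax:lmax) / sampling_rate
  k <- which.max(res$cc[, 1])
  delay <- lags[k]
  list(match = abs(delay) <= tol + 1e-12, delay = delay)
}

#' Aggregate qualifying pairwise cross-correlations (XCOV)
#'
#' Band-limits all trials of an ensemble, enumerates all M(M-1)/2 unordered
#' distinct-trial pairs, screens each pair with the zero-delay match filter,
#' and averages the energy-normalized cross-correlation functions of the K
#' qualifying pairs over lags within one period of the slowest sought rhythm
#' plus a 25% margin (so a period at the very edge of the search range still
#' forms an interior peak). The aggregate is corrected for the linear overlap
#' taper of finite-length cross-correlation (`n/(n - |l|)` per lag), which
#' would otherwise tilt periodicity peaks toward shorter lags; the
#' match-filter delay decision is made on the uncorrected functions.
#'
#' @param ensemble A [trial_ensemble()] with at least 2 trials.
#' @param band An [analysis_band()] (or its name).
#' @param tol Match-filter tolerance in seconds; default
#'   [default_match_tol()] (quarter period of the fastest sought rhythm).
#' @return An object of class `xcov_result`: `lags` (s), `values` (the
#'   aggregate, bounded in \[-1, 1\]), `M`, `n_candidate_pairs`, `K`,
#'   `pair_delays` (s, one per candidate pair), `frequency_axis` (1/lag for
#'   positive lags, `NA` elsewhere), `sampling_rate`, `band`.
#'   Throws an error of class `xcovpdf_no_pairs` when no pair qualifies;
#'   downstream, such a cell simply contributes no peak.
#' @examples
#' cfg <- synth_config(n_trials = 6, snr_db = 30, delay_jitter_sd = 0,
#'                     n_voxels = 1, n_subjects = 1, seed = 2)
#' ens <- simulate_cell(cfg, 1, 1)
#' xc <- aggregate_xcov(ens, analysis_band("delta"))
#' xc$K <= xc$n_candidate_pairs
#' @export
aggregate_xcov <- function(ensemble, band, tol = NULL) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  band <- as_band(band)
  if (is.null(tol)) tol <- default_match_tol(band)
  m <- ncol(ensemble$signals)
  if (m < 2)
    stop_xcovpdf("XCOV needs at least 2 trials", "xcovpdf_parameter_error")
  fs <- ensemble$sampling_rate
  n <- nrow(ensemble$signals)

  xf <- bandlimit(ensemble$signals, band, fs)
  lmax <- xcov_lmax(band, fs, n)
  res <- cpp_pairwise_xcov(xf, as.integer(lmax))
  lags <- (-lmax:lmax) / fs

  idx <- pair_indices(m)
  energy_ok <- res$energy[idx[, "i"]] > 0 & res$energy[idx[, "j"]] > 0
  # argmax lag of each pair's normalized cross-correlation
  best <- max.col(t(res$cc), ties.method = "first")
  delays <- lags[best]
  qualify <- energy_ok & abs(delays) <= tol + 1e-12
  K <- sum(qualify)
  if (K == 0L)
    stop_xcovpdf("no trial pair passed the zero-delay match filter",
                 "xcovpdf_no_pairs")
  # unbiased-overlap correction; a fixed per-lag factor, so correcting the
  # mean equals averaging corrected pair functions
  taper <- n / (n - abs(-lmax:lmax))
  values <- rowMeans(res$cc[, qualify, drop = FALSE]) * taper
  structure(
    list(lags = lags, values = values, M = m,
         n_candidate_pairs = nrow(idx), K = K,
         pair_delays = delays, qualified = qualify,
         frequency_axis = ifelse(lags > 0, 1 / lags, NA_real_),
         sampling_rate = fs, band = band$name,
         subject = ensemble$subject, voxel = ensemble$voxel),
    class = "xcov_result"
  )
}

#' @export
print.xcov_result <- function(x, ...) {
  cat(sprintf(
    "<xcov_result> %s band: M=%d trials, %d candidate pairs, K=%d aggregated\n",
    x$band, x$M, x$n_candidate_pairs, x$K))
  invisible(x)
}
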