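# Prominent-peak extraction from an XCOV function.
#
# The trivial zero-lag peak is excluded by restricting the search to lags of
# at least one period of the fastest sought rhythm (1/f_max); lags beyond
# 1/f_min would map to frequencies below the search range. The peak standing
# out the most -- by topographic prominence, i.e. height above the lowest
# saddle separating it from any higher point -- is converted to a frequency
# via f = 1/lag.

# Local maxima (strictly greater than both neighbors) of v, interior points.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
}

# Topographic prominence of each listed peak within the window v:
# height minus the higher of the two bases, where each base is the minimum
# of v between the peak and the nearest strictly higher point on that side
# (or the window edge if no higher point exists).
peak_prominences <- function(v, peaks) {
  vapply(peaks, function(p) {
    h <- v[p]
    left <- seq_len(p - 1)
    higher_l <- left[v[left] > h]
    base_l <- min(v[seq(if (length(higher_l)) max(higher_l) else 1, p)])
    right <- seq(p + 1, length(v))
    higher_r <- right[v[right] > h]
    base_r <- min(v[seq(p, if (length(higher_r)) min(higher_r) else length(v))])
    h - max(base_l, base_r)
  }, numeric(1))
}

#' Extract the prominent peak frequency of an XCOV function
#'
#' Finds the local maxima at positive lags corresponding to the band's
#' frequency search range, ranks them by topographic prominence, and returns
#' the top one as a frequency (`f = 1/lag`). Prominence is measured on the
#' whole nonnegative-lag half of the function (the zero-lag peak acts as the
#' left wall), so a peak near the search-window edge is not penalized by a
#' truncated basin. Near-ties in prominence (within `tie_tol`, relative) are
#' resolved toward the earliest peak (shortest lag), following the
#' autocorrelation convention that the earliest nontrivial peak marks the
#' period: a periodic aggregate repeats its peak at every multiple of the
#' period with near-identical prominence, and only the earliest of those is
#' the period itself. Absence of any local maximum is a valid outcome
#' (`frequency = NA`), not an error.
#'
#' @param x An [aggregate_xcov()] result.
#' @param band An [analysis_band()] (or its name); peaks are searched at lags
#'   in `[1/f_max, 1/f_min]`.
#' @param n_peaks How many ranked candidate peaks to report (the prominent
#'   peak is always the first).
#' @param tie_tol Relative prominence margin within which peaks count as
#'   tied (default 0.2). A generous margin is deliberate: a periodic
#'   aggregate repeats its peak at 2x, 3x the period with comparable
#'   prominence, and under noise the repeat can outgrow the fundamental by
#'   more than a few percent -- the pitch-estimation "octave error". Peaks
#'   of a genuinely different, weaker rhythm sit far below this margin.
#' @return An object of class `peak_sample`: `frequency` (Hz or `NA`),
#'   `prominence`, `lag` (s), `source` (subject, voxel), and `candidates`
#'   (data frame of the top `n_peaks` ranked peaks).
#' @examples
#' cfg <- synth_config(n_trials = 6, snr_db = 30, delay_jitter_sd = 0,
#'                     n_voxels = 1, n_subjects = 1, seed = 2)
#' xc <- aggregate_xcov(simulate_cell(cfg, 1, 1), "delta")
#' prominent_peak(xc, "delta")$frequency
#' @export
prominent_peak <- function(x, band, n_peaks = 1L, tie_tol = 0.2) {
  stopifnot(inherits(x, "xcov_result"))
  band <- as_band(band)
  fr <- band$search_range
  support <- which(x$lags >= 0)
  v <- x$values[support]
  lag_v <- x$lags[support]
  window <- lag_v >= 1 / fr[2] - 1e-12 & lag_v <= 1 / fr[1] + 1e-12
  pk <- local_maxima(v)
  pk <- pk[window[pk]]
  absent <- structure(
    list(frequency = NA_real_, prominence = NA_real_, lag = NA_real_,
         source = c(subject = x$subject, voxel = x$voxel),
         candidates = data.frame(frequency = numeric(0),
                                 prominence = numeric(0), lag = numeric(0))),
    class = "peak_sample")
  if (length(pk) == 0L) return(absent)
  prom <- peak_prominences(v, pk)
  # near-ties with the most prominent peak resolve to the earliest lag
  near <- prom >= (1 - tie_tol) * max(prom)
  best <- pk[near][which.min(lag_v[pk[near]])]
  ord <- order(pk != best, -prom, lag_v[pk])
  pk <- pk[ord]; prom <- prom[ord]
  keep <- seq_len(min(n_peaks, length(pk)))
  cand <- data.frame(frequency = 1 / lag_v[pk[keep]],
                     prominence = prom[keep],
                     lag = lag_v[pk[keep]])
  structure(
    list(frequency = cand$frequency[1], prominence = cand$prominence[1],
         lag = cand$lag[1],
         source = c(subject = x$subject, voxel = x$voxel),
         candidates = cand),
    class = "peak_sample")
}

#' @export
print.peak_sample <- function(x, ...) {
  if (is.na(x$frequency)) cat("<peak_sample> absent (no local maximum)\n")
  else cat(sprintf("<peak_sample> %.3f Hz (prominence %.4g)\n",
                   x$frequency, x$prominence))
  invisible(x)
}
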