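# Yes-no signal-detection behavior: the four response classes of a target
# identification task (hit, miss, false alarm, correct rejection) and the
# sensitivity index d' = z(hit rate) - z(false-alarm rate).

#' Behavioral response counts and d'
#'
#' @param n_hit,n_miss,n_fa,n_cr Nonnegative counts; target-present trials
#'   are `n_hit + n_miss` (>= 1), target-absent `n_fa + n_cr` (>= 1).
#' @return An object of class `behavioral_counts` with raw rates, edge-
#'   corrected rates (`1/(2n)` rule: a rate of 0 becomes `1/(2n)`, a rate of
#'   1 becomes `1 - 1/(2n)`), and the d' computed on the corrected rates.
#' @examples
#' behavioral_counts(45, 5, 8, 42)$dprime
#' @export
behavioral_counts <- function(n_hit, n_miss, n_fa, n_cr) {
  cnt <- c(n_hit, n_miss, n_fa, n_cr)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop_xcovpdf("counts must be nonnegative integers",
                 "xcovpdf_input_error")
  n_present <- n_hit + n_miss
  n_absent <- n_fa + n_cr
  if (n_present < 1 || n_absent < 1)
    stop_xcovpdf("need at least one target-present and one target-absent trial",
                 "xcovpdf_input_error")
  correct_rate <- function(k, n) {
    r <- k / n
    if (r == 0) 1 / (2 * n) else if (r == 1) 1 - 1 / (2 * n) else r
  }
  hr <- correct_rate(n_hit, n_present)
  fr <- correct_rate(n_fa, n_absent)
  structure(
    list(n_hit = n_hit, n_miss = n_miss, n_fa = n_fa, n_cr = n_cr,
         n_present = n_present, n_absent = n_absent,
         hit_rate_raw = n_hit / n_present, fa_rate_raw = n_fa / n_absent,
         hit_rate = hr, fa_rate = fr,
         dprime = qnorm(hr) - qnorm(fr)),
    class = "behavioral_counts")
}

#' @export
print.behavioral_counts <- function(x, ...) {
  cat(sprintf(
    "<behavioral_counts> hit %d/%d, fa %d/%d -> d' = %.3f\n",
    x$n_hit, x$n_present, x$n_fa, x$n_absent, x$dprime))
  invisible(x)
}

#' Yes-no sensitivity d'
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with `z` the standard normal
#' quantile. The counts method applies the `1/(2n)` edge correction before
#' the transformation; the rates method expects rates strictly inside (0, 1)
#' and applies no correction.
#'
#' @param x A [behavioral_counts()] object, or the hit rate.
#' @param fa_rate False-alarm rate (rates method only).
#' @param ... Unused.
#' @return d' (finite scalar).
#' @examples
#' dprime(0.9, 0.1)                      # 2 * qnorm(0.9)
#' dprime(behavioral_counts(20, 0, 0, 20))  # corrected, finite
#' @export
dprime <- function(x, ...) UseMethod("dprime")

#' @rdname dprime
#' @export
dprime.behavioral_counts <- function(x, ...) x$dprime

#' @rdname dprime
#' @export
dprime.numeric <- function(x, fa_rate, ...) {
  if (any(x <= 0) || any(x >= 1) || any(fa_rate <= 0) || any(fa_rate >= 1))
    stop_xcovpdf("rates must lie strictly inside (0, 1); use counts for edge correction",
                 "xcovpdf_input_error")
  qnorm(x) - qnorm(fa_rate)
}

#' Classify per-trial yes-no records
#'
#' Partitions trial records into the four response classes and the derived
#' correct (hit or correct rejection) / erroneous (miss or false alarm)
#' split; the partition is exhaustive and disjoint.
#'
#' @param trials Data frame with logical columns `target_present` and
#'   `yes_response`.
#' @return List with `counts` (a [behavioral_counts()]), `class` (factor per
#'   trial: hit / miss / fa / cr), and `correct` (logical per trial).
#' @examples
#' df <- data.frame(target_present = c(TRUE, TRUE, FALSE, FALSE),
#'                  yes_response   = c(TRUE, FALSE, TRUE, FALSE))
#' classify_responses(df)$class
#' @export
classify_responses <- function(trials) {
  if (!is.data.frame(trials) ||
      !all(c("target_present", "yes_response") %in% names(trials)))
    stop_xcovpdf("`trials` needs columns target_present and yes_response",
                 "xcovpdf_input_error")
  tp <- as.logical(trials$target_present)
  yes <- as.logical(trials$yes_response)
  if (anyNA(tp) || anyNA(yes))
    stop_xcovpdf("target_present / yes_response must be non-missing logicals",
                 "xcovpdf_input_error")
  cls <- ifelse(tp & yes, "hit",
         ifelse(tp & !yes, "miss",
         ifelse(!tp & yes, "fa", "cr")))
  cls <- factor(cls, levels = c("hit", "miss", "fa", "cr"))
  counts <- behavioral_counts(sum(cls == "hit"), sum(cls == "miss"),
                              sum(cls == "fa"), sum(cls == "cr"))
  list(counts = counts, class = cls, correct = cls %in% c("hit", "cr"))
}
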