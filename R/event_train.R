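#' Build a periodic chunk/digit event train
#'
#' Constructs the stimulus timing skeleton the generator is locked to:
#' two-digit chunks presented at a fixed `chunk_rate`, the first digit at each
#' chunk onset and the second `digit_offset` seconds later. The chunk rate is
#' set purely by the gap between chunks, so the within-chunk timing (and hence
#' the bimodal structure of consecutive digit-onset intervals) is identical
#' across rates.
#'
#' @param chunk_rate Chunk presentation rate in Hz (> 0). The study conditions
#'   are 1.8 Hz (inside the 0.5-2 Hz delta band) and 2.6 Hz (outside).
#' @param n_chunks Number of chunks (>= 1).
#' @param digit_offset Onset delay of the second digit within a chunk, in
#'   seconds; must lie strictly inside one chunk period.
#' @return An object of class `event_train`: list with `chunk_rate`,
#'   `chunk_onsets` (s), `digit_onsets` (s), `duration` (s).
#' @examples
#' tr <- make_event_train(2, 5, 0.2)
#' tr$chunk_onsets            # 0.0 0.5 1.0 1.5 2.0
#' unique(diff(tr$digit_onsets))  # 0.2 0.3 : bimodal
#' @export
make_event_train <- function(chunk_rate, n_chunks, digit_offset) {
  if (!is.numeric(chunk_rate) || length(chunk_rate) != 1L || chunk_rate <= 0)
    stop_xcovpdf("`chunk_rate` must be a positive scalar (Hz)",
                 "xcovpdf_parameter_error")
  if (!is.numeric(n_chunks) || length(n_chunks) != 1L || n_chunks < 1 ||
      n_chunks != round(n_chunks))
    stop_xcovpdf("`n_chunks` must be a positive integer",
                 "xcovpdf_parameter_error")
  period <- 1 / chunk_rate
  if (!is.numeric(digit_offset) || length(digit_offset) != 1L ||
      digit_offset <= 0 || digit_offset >= period)
    stop_xcovpdf(
      sprintf("`digit_offset` must lie strictly inside one chunk period (0, %g s)",
              period),
      "xcovpdf_parameter_error")
  chunk_onsets <- (seq_len(n_chunks) - 1) * period
  digit_onsets <- sort(c(chunk_onsets, chunk_onsets + digit_offset))
  structure(
    list(chunk_rate = chunk_rate,
         chunk_onsets = chunk_onsets,
         digit_onsets = digit_onsets,
         duration = n_chunks * period),
    class = "event_train"
  )
}

#' Inter-onset intervals of an event train
#'
#' Returns the consecutive digit-onset intervals together with the
#' first-digit-to-first-digit interval (one chunk period). For a two-digit
#' chunk train these take at most three distinct values: the chunk period, the
#' within-chunk offset, and the across-gap interval; the consecutive intervals
#' alone are bimodal whenever `digit_offset` differs from half the period.
#'
#' @param train An [make_event_train()] result.
#' @return List with `consecutive` (digit-onset differences, s) and
#'   `distinct` (sorted unique values including the chunk period, s).
#' @export
digit_intervals <- function(train) {
  stopifnot(inherits(train, "event_train"))
  consec <- diff(train$digit_onsets)
  distinct <- sort(unique(round(c(1 / train$chunk_rate, consec), 12)))
  list(consecutive = consec, distinct = distinct)
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf(
    "<event_train> %g Hz chunk rate, %d chunks (%d digit onsets), %.3f s\n",
    x$chunk_rate, length(x$chunk_onsets), length(x$digit_onsets), x$duration))
  invisible(x)
}
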