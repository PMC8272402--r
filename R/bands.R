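#' Analysis frequency bands
#'
#' Defines the two analysis bands used throughout the pipeline. The `delta`
#' band targets phrase-rate (chunk-rate) periodicity: signals are low-pass
#' filtered at 6 Hz and XCOV peaks are searched in the 1-4 Hz range. The
#' `theta` band targets the faster digit-rate periodicity: signals are
#' band-pass filtered to 2-10 Hz and peaks are searched in 2-6 Hz. Filter
#' passbands are deliberately wider than the expected periodicities so the
#' cross-correlation analysis, not the filter, determines the peak locations.
#'
#' The neural delta band proper is reported as 0.5-2 Hz
#' (`delta_band_definition`); the wider 1-4 Hz search range captures peaks at
#' and just outside its upper edge.
#'
#' @param name `"delta"` or `"theta"`.
#' @return An object of class `analysis_band`: a list with `name`,
#'   `filter_spec` (type and corner frequencies in Hz), `search_range`
#'   (`c(f_min, f_max)` in Hz) and `delta_band_definition` (reporting only).
#' @examples
#' analysis_band("delta")$search_range
#' @export
analysis_band <- function(name = c("delta", "theta")) {
  name <- match.arg(name)
  spec <- switch(name,
    delta = list(
      filter_spec = list(type = "low", cutoff = 6),
      search_range = c(1, 4)
    ),
    theta = list(
      filter_spec = list(type = "pass", cutoff = c(2, 10)),
      search_range = c(2, 6)
    )
  )
  structure(
    list(name = name,
         filter_spec = spec$filter_spec,
         search_range = spec$search_range,
         delta_band_definition = c(0.5, 2)),
    class = "analysis_band"
  )
}

#' @export
print.analysis_band <- function(x, ...) {
  co <- paste(x$filter_spec$cutoff, collapse = "-")
  cat(sprintf("<analysis_band> %s: %s filter %s Hz, search range [%g, %g] Hz\n",
              x$name, x$filter_spec$type, co,
              x$search_range[1], x$search_range[2]))
  invisible(x)
}

#' Default zero-delay match-filter tolerance for a band
#'
#' Quarter period of the fastest frequency in the band's search range: a pair
#' whose cross-correlation peaks within this lag of zero behaves like an
#' autocorrelation, while a pair one cycle off (at any sought rate) does not.
#'
#' @param band An [analysis_band()].
#' @return Tolerance in seconds (delta: 0.0625 s, theta: ~0.042 s).
#' @export
default_match_tol <- function(band) {
  stopifnot(inherits(band, "analysis_band"))
  1 / (4 * band$search_range[2])
}

as_band <- function(band) {
  if (inherits(band, "analysis_band")) band else analysis_band(band)
}
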