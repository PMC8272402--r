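#' Read a structured-text analysis configuration
#'
#' Loads a YAML (or JSON) file describing a full analysis: the generator
#' settings, the analysis band, and the pipeline options, ready to hand to
#' [run_condition()].
#'
#' The file may contain a `generator` block (any [synth_config()] argument),
#' and top-level `band` (`"delta"`/`"theta"`), `tol` (s), `bin_width` (Hz),
#' `gmm_order` and `chunk_rate` entries; everything is optional and falls
#' back to the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `config` (a [synth_config()]), `band` (an
#'   [analysis_band()]), `tol`, `bin_width`, `gmm_order`, `chunk_rate`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("band: delta", "generator:", "  chunk_rate: 1.8",
#'              "  n_voxels: 2", "  n_subjects: 2", "  n_trials: 4",
#'              "  seed: 7"), f)
#' cl <- load_config(f)
#' cl$config$n_trials
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_xcovpdf(sprintf("config file not found: %s", path),
                 "xcovpdf_input_error")
  raw <- if (grepl("[.]json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  gen <- raw$generator %||% list()
  bad <- setdiff(names(gen), names(formals(synth_config)))
  if (length(bad))
    stop_xcovpdf(sprintf("unknown generator settings: %s",
                         paste(bad, collapse = ", ")),
                 "xcovpdf_input_error")
  cfg <- do.call(synth_config, gen)
  band <- analysis_band(raw$band %||% "delta")
  list(config = cfg,
       band = band,
       tol = raw$tol %||% default_match_tol(band),
       bin_width = raw$bin_width %||% 0.1,
       gmm_order = as.integer(raw$gmm_order %||% 3L),
       chunk_rate = raw$chunk_rate %||% cfg$chunk_rate)
}

#' Run a condition described by a configuration file
#'
#' Thin wrapper: [load_config()] then [run_condition()].
#'
#' @param path Configuration file path (see [load_config()]).
#' @param out_dir Optional artifact directory.
#' @return A `condition_report`.
#' @export
run_condition_file <- function(path, out_dir = NULL) {
  cl <- load_config(path)
  run_condition(cl$config, band = cl$band, chunk_rate = cl$chunk_rate,
                tol = cl$tol, bin_width = cl$bin_width,
                gmm_order = cl$gmm_order, out_dir = out_dir)
}
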