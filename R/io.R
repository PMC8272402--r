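# Writers and readers for pipeline artifacts.
#
# Datasets travel either as a long-format CSV (subject, voxel, trial,
# sample_index, value) or as a flat little-endian double array ("bin"), each
# with a JSON sidecar carrying the sampling rate, labels, dimensions and a
# config echo. Reports and PDFs are JSON; histograms and XCOV functions are
# CSV.

#' Write a source dataset to disk
#'
#' @param dataset A `source_dataset`.
#' @param dir Output directory (created if missing).
#' @param format `"csv"` (long format, readable anywhere) or `"bin"` (flat
#'   double array; compact for large ensembles).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("csv", "bin")) {
  stopifnot(inherits(dataset, "source_dataset"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- dataset$config
  n <- nrow(dataset$cells[[1]]$signals)
  meta <- list(format = format,
               sampling_rate = cfg$sampling_rate,
               n_subjects = cfg$n_subjects, n_voxels = cfg$n_voxels,
               n_trials = cfg$n_trials, n_samples = n,
               condition = dataset$condition,
               response_class = dataset$response_class,
               roi_name = dataset$roi_name,
               seed = cfg$seed, config = unclass(cfg))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 12)
  if (format == "csv") {
    tabs <- lapply(dataset$cells, function(cell) {
      data.table::data.table(
        subject = cell$subject, voxel = cell$voxel,
        trial = rep(seq_len(ncol(cell$signals)), each = n),
        sample_index = rep(seq_len(n), times = ncol(cell$signals)),
        value = as.vector(cell$signals))
    })
    data.table::fwrite(data.table::rbindlist(tabs),
                       file.path(dir, "signals.csv"))
  } else {
    con <- file(file.path(dir, "signals.bin"), "wb")
    on.exit(close(con))
    for (cell in dataset$cells)
      writeBin(as.vector(cell$signals), con, size = 8, endian = "little")
  }
  invisible(dir)
}

#' Read a source dataset written by [write_dataset()]
#'
#' @param dir Directory containing `meta.json` and the signals file.
#' @return A `source_dataset`.
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(synth_config, meta$config[setdiff(names(meta$config),
                                                   character(0))])
  n <- meta$n_samples
  m <- meta$n_trials
  cells <- vector("list", meta$n_subjects * meta$n_voxels)
  nm <- character(length(cells))
  if (meta$format == "csv") {
    dt <- data.table::fread(file.path(dir, "signals.csv"))
    k <- 0L
    for (j in seq_len(meta$n_voxels)) {
      for (i in seq_len(meta$n_subjects)) {
        k <- k + 1L
        sub <- dt[dt$subject == i & dt$voxel == j, ]
        sig <- matrix(sub$value[order(sub$trial, sub$sample_index)], n, m)
        cells[[k]] <- trial_ensemble(sig, meta$sampling_rate, i, j,
                                     meta$condition, meta$response_class)
        nm[k] <- sprintf("s%02d_v%02d", i, j)
      }
    }
  } else {
    con <- file(file.path(dir, "signals.bin"), "rb")
    on.exit(close(con))
    k <- 0L
    for (j in seq_len(meta$n_voxels)) {
      for (i in seq_len(meta$n_subjects)) {
        k <- k + 1L
        sig <- matrix(readBin(con, "double", n * m, size = 8,
                              endian = "little"), n, m)
        cells[[k]] <- trial_ensemble(sig, meta$sampling_rate, i, j,
                                     meta$condition, meta$response_class)
        nm[k] <- sprintf("s%02d_v%02d", i, j)
      }
    }
  }
  names(cells) <- nm
  structure(
    list(cells = cells, n_subjects = meta$n_subjects,
         n_voxels = meta$n_voxels, train = config_train(cfg), config = cfg,
         condition = meta$condition, response_class = meta$response_class,
         roi_name = meta$roi_name),
    class = "source_dataset")
}

#' Write an XCOV function as CSV (+ optional JSON bookkeeping)
#'
#' @param x An [aggregate_xcov()] result.
#' @param file CSV path (columns lag, value).
#' @param json_file Optional JSON path for `M`, `n_candidate_pairs`, `K` and
#'   the prominent peak.
#' @param band Band used for the peak in the JSON sidecar.
#' @return `file`, invisibly.
#' @export
write_xcov <- function(x, file, json_file = NULL, band = x$band) {
  stopifnot(inherits(x, "xcov_result"))
  data.table::fwrite(data.frame(lag = x$lags, value = x$values), file)
  if (!is.null(json_file)) {
    pk <- prominent_peak(x, band)
    jsonlite::write_json(
      list(M = x$M, n_candidate_pairs = x$n_candidate_pairs, K = x$K,
           peak_frequency = pk$frequency, peak_prominence = pk$prominence),
      json_file, auto_unbox = TRUE, pretty = TRUE, digits = 12, na = "null")
  }
  invisible(file)
}

#' Write a periodicity histogram as CSV
#'
#' @param h A [build_histogram()] result.
#' @param file CSV path (columns bin_left, bin_right, count, normalized).
#' @return `file`, invisibly.
#' @export
write_histogram <- function(h, file) {
  stopifnot(inherits(h, "periodicity_histogram"))
  ne <- length(h$bin_edges)
  data.table::fwrite(
    data.frame(bin_left = h$bin_edges[-ne], bin_right = h$bin_edges[-1],
               count = h$counts, normalized = h$normalized),
    file)
  invisible(file)
}

#' Write a periodicity PDF as JSON
#'
#' @param pdf A [periodicity_pdf()].
#' @param file JSON path.
#' @return `file`, invisibly.
#' @export
write_pdf_json <- function(pdf, file) {
  stopifnot(inherits(pdf, "periodicity_pdf"))
  jsonlite::write_json(
    list(converged = pdf$converged, P = pdf$P, n = pdf$n,
         components = pdf$components,
         prominent = pdf$prominent, prominent_mu = pdf$prominent_mu,
         prominent_sigma = pdf$prominent_sigma,
         prominent_var = pdf$prominent_var,
         search_range = pdf$search_range),
    file, auto_unbox = TRUE, pretty = TRUE, digits = 12, na = "null")
  invisible(file)
}

# Strip classes/function-free representation for JSON serialization.
report_payload <- function(x) {
  if (inherits(x, "periodicity_histogram"))
    return(list(bin_edges = x$bin_edges, counts = x$counts,
                normalized = x$normalized, scale_total = x$scale_total,
                n_in_range = x$n_in_range, P = x$P))
  if (inherits(x, "periodicity_pdf"))
    return(list(converged = x$converged, P = x$P, n = x$n,
                components = x$components, prominent = x$prominent,
                prominent_mu = x$prominent_mu,
                prominent_sigma = x$prominent_sigma,
                prominent_var = x$prominent_var,
                search_range = x$search_range))
  if (inherits(x, "pdf_comparison"))
    return(list(kld = x$kld, shift_applied = x$shift_applied))
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, report_payload))
  x
}

#' Write a condition or study report as JSON
#'
#' Stable key order, floats at 12 significant digits, no timestamps: the
#' same configuration and seed produce byte-identical output.
#'
#' @param report A `condition_report` or `study_report`.
#' @param file JSON path.
#' @return `file`, invisibly.
#' @export
write_report <- function(report, file) {
  jsonlite::write_json(report_payload(unclass(report)), file,
                       auto_unbox = TRUE, pretty = TRUE, digits = 12,
                       na = "null", dataframe = "columns")
  invisible(file)
}
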