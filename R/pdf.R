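# Call an mclust function with the mclust namespace as the calling frame:
# Mclust() and hc() resolve helper functions (mclustBIC, hcV, ...) in the
# caller's environment, which fails from another package's namespace.
mclust_call <- function(fn, ...) {
  do.call(getExportedValue("mclust", fn), list(...),
          envir = asNamespace("mclust"))
}

# Periodicity density functions.
#
# One prominent XCOV peak per (voxel, subject) cell is pooled across a
# dataset: the distribution of these peak frequencies, modeled as a
# third-order Gaussian mixture, is the periodicity density function (PDF) of
# the ROI. Its goodness is summarized by P (fraction of the L x N cells with
# an in-range peak), and the mean and spread of the prominent mixture
# component; Bias measures how far that mean sits from the driving acoustic
# chunk rate.

#' Collect prominent peak frequencies across a dataset
#'
#' Runs [aggregate_xcov()] and [prominent_peak()] on every (subject, voxel)
#' cell. Cells with no qualifying pair or no local maximum contribute an
#' absent sample (`NA` frequency) which is recorded but excluded from the
#' in-range count.
#'
#' @param dataset A [simulate_dataset()] result (or any `source_dataset`).
#' @param band An [analysis_band()] (or its name).
#' @param tol Match-filter tolerance in seconds; default
#'   [default_match_tol()].
#' @return A data frame with one row per cell: `subject`, `voxel`,
#'   `frequency` (Hz or `NA`), `prominence`, `M`, `n_candidate_pairs`, `K`.
#' @export
collect_peaks <- function(dataset, band, tol = NULL) {
  stopifnot(inherits(dataset, "source_dataset"))
  if (length(dataset$cells) == 0L)
    stop_xcovpdf("dataset has no cells", "xcovpdf_input_error")
  band <- as_band(band)
  rows <- lapply(dataset$cells, function(cell) {
    xc <- tryCatch(aggregate_xcov(cell, band, tol),
                   xcovpdf_no_pairs = function(e) NULL)
    if (is.null(xc)) {
      m <- ncol(cell$signals)
      data.frame(subject = cell$subject, voxel = cell$voxel,
                 frequency = NA_real_, prominence = NA_real_,
                 M = m, n_candidate_pairs = n_candidate_pairs(m), K = 0L)
    } else {
      pk <- prominent_peak(xc, band)
      data.frame(subject = cell$subject, voxel = cell$voxel,
                 frequency = pk$frequency, prominence = pk$prominence,
                 M = xc$M, n_candidate_pairs = xc$n_candidate_pairs,
                 K = xc$K)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

in_range_frequencies <- function(peaks, band) {
  band <- as_band(band)
  f <- if (is.data.frame(peaks)) peaks$frequency else as.numeric(peaks)
  f <- f[is.finite(f)]
  f[f >= band$search_range[1] & f <= band$search_range[2]]
}

#' Histogram of in-range peak frequencies
#'
#' Bins tile the band's search range; only in-range peaks are counted, and
#' heights are normalized to the total number of cells (L x N), so the
#' histogram integrates to P, not to 1.
#'
#' @param peaks A [collect_peaks()] data frame or a numeric vector of peak
#'   frequencies (Hz, `NA` = absent).
#' @param band An [analysis_band()] (or its name).
#' @param bin_width Bin width in Hz (> 0); display/reporting resolution only
#'   -- P does not depend on it.
#' @param scale_total The L x N cell count; defaults to the number of rows
#'   (or elements) of `peaks`.
#' @return An object of class `periodicity_histogram`: `bin_edges`, `counts`,
#'   `normalized` (= counts / scale_total), `scale_total`, `n_in_range`, `P`.
#' @export
build_histogram <- function(peaks, band, bin_width = 0.1,
                            scale_total = NULL) {
  if (bin_width <= 0)
    stop_xcovpdf("`bin_width` must be positive", "xcovpdf_parameter_error")
  band <- as_band(band)
  if (is.null(scale_total))
    scale_total <- if (is.data.frame(peaks)) nrow(peaks) else length(peaks)
  f <- in_range_frequencies(peaks, band)
  fr <- band$search_range
  edges <- seq(fr[1], fr[2], by = bin_width)
  if (edges[length(edges)] < fr[2]) edges <- c(edges, fr[2])
  bin <- findInterval(f, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  structure(
    list(bin_edges = edges, counts = counts,
         normalized = counts / scale_total,
         scale_total = scale_total, n_in_range = length(f),
         P = length(f) / scale_total),
    class = "periodicity_histogram")
}

#' @export
print.periodicity_histogram <- function(x, ...) {
  cat(sprintf(
    "<periodicity_histogram> %d bins over [%g, %g] Hz, %d/%d in range (P = %.3f)\n",
    length(x$counts), min(x$bin_edges), max(x$bin_edges),
    x$n_in_range, x$scale_total, x$P))
  invisible(x)
}

#' Construct a periodicity PDF (Gaussian mixture over frequency)
#'
#' Low-level constructor, mainly useful for building reference mixtures;
#' [fit_gmm()] produces these from data.
#'
#' @param weights,means,sds Component parameters (equal length; weights sum
#'   to 1, sds positive).
#' @param P Fraction of cells with an in-range peak (may be `NA`).
#' @param n Number of samples behind the fit.
#' @param search_range Frequency range (Hz) the mixture describes.
#' @param converged Logical convergence flag.
#' @return An object of class `periodicity_pdf`. The prominent component is
#'   the one with the largest weight (ties broken toward the narrower sd);
#'   its mean and sd are exposed as `prominent_mu` / `prominent_sigma`.
#' @export
periodicity_pdf <- function(weights, means, sds, P = NA_real_,
                            n = NA_integer_, search_range = c(1, 4),
                            converged = TRUE) {
  stopifnot(length(weights) == length(means),
            length(means) == length(sds))
  if (converged) {
    if (abs(sum(weights) - 1) > 1e-6)
      stop_xcovpdf("mixture weights must sum to 1", "xcovpdf_parameter_error")
    if (any(sds <= 0))
      stop_xcovpdf("mixture sds must be positive", "xcovpdf_parameter_error")
  }
  prominent <- order(-weights, sds)[1]
  structure(
    list(components = data.frame(weight = weights, mean = means, sd = sds),
         converged = converged,
         P = P, n = n,
         prominent = prominent,
         prominent_mu = means[prominent],
         prominent_sigma = sds[prominent],
         prominent_var = sds[prominent]^2,
         search_range = search_range),
    class = "periodicity_pdf")
}

nonconverged_pdf <- function(P, n, order, search_range) {
  structure(
    list(components = data.frame(weight = numeric(0), mean = numeric(0),
                                 sd = numeric(0)),
         converged = FALSE, P = P, n = n,
         prominent = NA_integer_, prominent_mu = NA_real_,
         prominent_sigma = NA_real_, prominent_var = NA_real_,
         search_range = search_range),
    class = "periodicity_pdf")
}

#' Fit a third-order Gaussian mixture to peak frequencies
#'
#' Fits the mixture by maximum likelihood on the raw in-range peak
#' frequencies (sample-level EM via \pkg{mclust}; equal- and
#' unequal-variance parameterizations compared by BIC), which estimates the
#' same density the normalized histogram displays but is bin-width-free. A sample smaller than `min_n`, or an EM failure (which a
#' degenerate, near-empty histogram produces), yields a non-converged result
#' with absent mu/sigma -- a reported state, never an exception, so batch
#' runs over many ROIs complete. When the unregularized fit degenerates
#' (grid-discretized frequencies can collapse a component's variance), a
#' conjugate-prior regularized fit is tried before giving up.
#'
#' @param freqs Numeric vector of in-range peak frequencies (Hz); `NA`s are
#'   dropped.
#' @param order Number of mixture components (default 3).
#' @param min_n Minimum sample size to attempt a fit (default `3 * order`).
#' @param scale_total If given, P is computed as `length(freqs) /
#'   scale_total`.
#' @param search_range Frequency range annotation (Hz).
#' @return A [periodicity_pdf()].
#' @examples
#' f <- rnorm(380, 1.8, 0.05)
#' fit_gmm(f, scale_total = 380)$prominent_mu
#' @export
fit_gmm <- function(freqs, order = 3L, min_n = 3L * order,
                    scale_total = NULL, search_range = c(1, 4)) {
  freqs <- freqs[is.finite(freqs)]
  n <- length(freqs)
  P <- if (is.null(scale_total)) NA_real_ else n / scale_total
  if (n < min_n) return(nonconverged_pdf(P, n, order, search_range))
  fit_ok <- function(fit) {
    !is.null(fit) && is.finite(fit$loglik) &&
      length(fit$parameters$pro) == order &&
      all(is.finite(fit$parameters$pro)) &&
      all(is.finite(fit$parameters$mean)) &&
      all(sqrt(fit$parameters$variance$sigmasq) > 1e-6)
  }
  # model-based hierarchical initialization on the raw values: the
  # univariate default start can merge well-separated components
  init <- tryCatch(
    list(hcPairs = mclust_call("hc", freqs, modelName = "V", use = "VARS")),
    error = function(e) NULL)
  # equal- and unequal-variance parameterizations compete by BIC: the
  # unequal-variance model captures a tight periodicity component over a
  # broad background, while the equal-variance model keeps the fit centered
  # when the sample is effectively unimodal
  try_fit <- function(prior, initialization) {
    tryCatch(
      suppressWarnings(mclust_call("Mclust", freqs, G = order,
                                   modelNames = c("E", "V"), prior = prior,
                                   verbose = FALSE,
                                   initialization = initialization)),
      error = function(e) NULL)
  }
  # a mild conjugate prior on the component variances keeps the
  # unequal-variance model viable when peak frequencies are concentrated on
  # a few lag-grid values (where unregularized EM collapses a variance and
  # the model choice would silently fall back to equal variances)
  fit <- try_fit(mclust_call("priorControl"), init)
  if (!fit_ok(fit)) fit <- try_fit(mclust_call("priorControl"), NULL)
  if (!fit_ok(fit)) fit <- try_fit(NULL, init)
  if (!fit_ok(fit)) return(nonconverged_pdf(P, n, order, search_range))
  sds <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sds) == 1L) sds <- rep(sds, order)
  periodicity_pdf(as.numeric(fit$parameters$pro),
                  as.numeric(fit$parameters$mean), as.numeric(sds),
                  P = P, n = n, search_range = search_range)
}

#' Mixture density of a periodicity PDF
#'
#' @param pdf A converged [periodicity_pdf()].
#' @param x Frequencies (Hz) at which to evaluate the density.
#' @return Numeric vector of densities.
#' @export
pdf_density <- function(pdf, x) {
  stopifnot(inherits(pdf, "periodicity_pdf"))
  if (!pdf$converged)
    stop_xcovpdf("cannot evaluate a non-converged periodicity PDF",
                 "xcovpdf_comparison_undefined")
  comp <- pdf$components
  out <- numeric(length(x))
  for (k in seq_len(nrow(comp)))
    out <- out + comp$weight[k] * dnorm(x, comp$mean[k], comp$sd[k])
  out
}

#' @export
print.periodicity_pdf <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<periodicity_pdf> non-converged (n = %s, P = %s)\n",
                x$n, format(x$P, digits = 3)))
  } else {
    cat(sprintf(
      "<periodicity_pdf> %d components; prominent mu = %.3f Hz, sigma = %.3f Hz, P = %s\n",
      nrow(x$components), x$prominent_mu, x$prominent_sigma,
      format(x$P, digits = 3)))
  }
  invisible(x)
}

#' Goodness of a periodicity PDF against the acoustic chunk rate
#'
#' @param pdf A [periodicity_pdf()].
#' @param chunk_rate Driving acoustic chunk rate in Hz.
#' @return List with `P`, `mu` (prominent component mean, Hz), `sigma` (its
#'   sd, Hz), `sigma2` (its variance), and `bias` (`|mu - chunk_rate|`, Hz).
#'   For a non-converged PDF, `P` is still reported and the rest are `NA`.
#' @examples
#' p <- periodicity_pdf(1, 2.0, 0.1, P = 0.6)
#' goodness(p, 1.8)$bias  # 0.2
#' @export
goodness <- function(pdf, chunk_rate) {
  stopifnot(inherits(pdf, "periodicity_pdf"))
  if (!pdf$converged)
    return(list(P = pdf$P, mu = NA_real_, sigma = NA_real_,
                sigma2 = NA_real_, bias = NA_real_))
  list(P = pdf$P, mu = pdf$prominent_mu, sigma = pdf$prominent_sigma,
       sigma2 = pdf$prominent_var,
       bias = abs(pdf$prominent_mu - chunk_rate))
}

#' Summarize goodness across ROIs
#'
#' @param goodness_list List of [goodness()] results (one per ROI).
#' @return List with mean and variance of `bias` and of `P` across ROIs
#'   (`NA` entries dropped).
#' @export
summarize_goodness <- function(goodness_list) {
  b <- vapply(goodness_list, function(g) g$bias, numeric(1))
  p <- vapply(goodness_list, function(g) g$P, numeric(1))
  list(bias_mean = mean(b, na.rm = TRUE), bias_var = var(b[!is.na(b)]),
       P_mean = mean(p, na.rm = TRUE), P_var = var(p[!is.na(p)]))
}

#' Kullback-Leibler divergence between two periodicity PDFs
#'
#' Both mixtures are evaluated on a common frequency grid spanning the search
#' range, floored, and renormalized to unit mass; the divergence is
#' `sum(p * log(p / q))` over the grid. `shift` translates `p`'s frequency
#' axis before evaluation (e.g. `shift = -0.8` moves a 2.6-Hz-centered PDF
#' onto 1.8 Hz), so density functions of different chunk-rate conditions can
#' be compared in shape.
#'
#' @param p,q Converged [periodicity_pdf()]s; `p` is the comparison PDF, `q`
#'   the reference.
#' @param shift Frequency translation of `p` in Hz (default 0).
#' @param grid_n Number of grid points (default 512).
#' @param floor_density Density floor applied before renormalization.
#' @return An object of class `pdf_comparison`: `kld` (nonnegative), `shift`,
#'   `grid`.
#' @examples
#' p <- periodicity_pdf(1, 1.8, 0.1)
#' kld(p, p)$kld  # 0
#' @export
kld <- function(p, q, shift = 0, grid_n = 512L, floor_density = 1e-12) {
  stopifnot(inherits(p, "periodicity_pdf"), inherits(q, "periodicity_pdf"))
  if (!p$converged || !q$converged)
    stop_xcovpdf("KLD requires two converged periodicity PDFs",
                 "xcovpdf_comparison_undefined")
  fr <- q$search_range
  grid <- seq(fr[1], fr[2], length.out = grid_n)
  pd <- pmax(pdf_density(p, grid - shift), floor_density)
  qd <- pmax(pdf_density(q, grid), floor_density)
  pd <- pd / sum(pd)
  qd <- qd / sum(qd)
  structure(
    list(kld = sum(pd * log(pd / qd)), shift_applied = shift, grid = grid),
    class = "pdf_comparison")
}

#' @export
print.pdf_comparison <- function(x, ...) {
  cat(sprintf("<pdf_comparison> KLD = %.4f (shift %+g Hz)\n",
              x$kld, x$shift_applied))
  invisible(x)
}
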