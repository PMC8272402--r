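# xcovpdf

Trial-pair cross-correlation analysis of periodicity in multi-trial neural
signals, for researchers studying cortical tracking of rhythmic structure in
speech (and anyone else who needs to ask "does this small bundle of noisy
trials carry a periodicity, and at what frequency?").

## The problem and the method

Source-level MEG/EEG analyses often end up with a small number M of usable
trials per (subject, voxel, condition, response-class) cell — too few for
reliable inter-trial phase coherence, too noisy for per-trial
autocorrelation. The **XCOV** measure works around this by exploiting the
M(M−1)/2 unordered trial *pairs*:

1. band-limit every trial (zero-phase order-4 Butterworth; 6-Hz low-pass for
   the δ analysis, 2–10 Hz band-pass for θ);
2. screen each pair with a **zero-delay match filter**: the pair qualifies
   iff its energy-normalized cross-correlation peaks within `tol` s of zero
   lag (default `1/(4 f_max)`, i.e. a quarter period of the fastest sought
   rhythm);
3. average the K qualifying pairwise cross-correlations. The aggregate
   behaves like an autocorrelation — peak at zero, earliest nontrivial peak
   at the period;
4. take the most **prominent** local maximum at lags in
   `[1/f_max, 1/f_min]` and convert it to a frequency, `f = 1/lag`.

Pooling one peak per (voxel, subject) cell over an ROI gives at most L × N
datapoints. Their distribution — the **periodicity density function** — is
modeled as a third-order Gaussian mixture (EM via mclust), summarized by

* `P` — fraction of the L × N cells with an in-range peak,
* `μ`, `σ` — mean and spread of the heaviest ("prominent") mixture
  component,
* `Bias = |μ − chunk rate|` — distance of the neural periodicity from the
  driving acoustic chunk rate,

and compared across ROIs/hemispheres/conditions by Kullback–Leibler
divergence on a common frequency grid (optionally after shifting one PDF
along the frequency axis so different stimulus rates can be compared in
shape). Behavioral sensitivity uses the yes–no model,
`d′ = z(hit rate) − z(false-alarm rate)` with the `1/(2n)` edge correction.

A synthetic-data generator produces the multi-trial source datasets the
analysis assumes — chunk-locked Gamma-kernel responses, a digit-rate
component with bimodal onset structure, 1/f^χ noise at a controlled SNR,
trial delay and per-event phase jitter — with per-trial seed substreams, so
every stage is testable end to end. See the methods vignette
(`vignettes/xcov-periodicity-methods.Rmd`) for the model, parameter choices
and limitations.

## A worked example

```r
library(xcovpdf)

cfg <- synth_config(chunk_rate = 1.8, n_voxels = 4, n_subjects = 4,
                    n_trials = 8, snr_db = 10, seed = 42)
ds  <- simulate_dataset(cfg)

xc <- aggregate_xcov(ds$cells[[1]], "delta")
xc
#> <xcov_result> delta band: M=8 trials, 28 candidate pairs, K=27 aggregated
prominent_peak(xc, "delta")
#> <peak_sample> 1.880 Hz (prominence 0.6658)

peaks <- collect_peaks(ds, "delta")
fit <- fit_gmm(peaks$frequency, scale_total = nrow(peaks),
               search_range = c(1, 4))
fit
#> <periodicity_pdf> 3 components; prominent mu = 1.787 Hz, sigma = 0.016 Hz, P = 1
goodness(fit, chunk_rate = 1.8)$bias
#> [1] 0.01290582

simulate_behavior(0.86, 0.14, 50, 50, seed = 3)
#> <behavioral_counts> hit 45/50, fa 9/50 -> d' = 2.197
```

27 of the 28 candidate pairs pass the match filter; the aggregate's
prominent peak sits at 1.88 Hz in this single cell, and pooling all 16
cells tightens the prominent mixture component to μ = 1.79 Hz (σ = 0.016),
a Bias of 0.013 Hz from the 1.8-Hz driving rate with every cell
contributing an in-range peak (P = 1).

`run_condition()` chains these stages for one dataset (plus simulated
behavior), and `run_study()` runs the two chunk-rate conditions (1.8 Hz
inside the δ band, 2.6 Hz outside), compares their PDFs by shifted and
unshifted KLD, and tabulates the d′ / Bias / P correspondence.

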