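# motrace

Single-molecule motility analysis for processive cellulases measured with
surface-coupled optical tweezers.

## The problem

A cellobiohydrolase tethered between a trapped bead and an immobilised
cellulose fibril drags the bead as it processively hydrolyses the chain.
The bead position along the motility axis, sampled at 3–5 kHz, records the
enzyme's progress at nanometre resolution — but the motility signal
(~0.1–0.2 nm/s) is buried under Brownian position noise, instrumental drift
of comparable rate, and occasional abrupt 5–20 nm displacements completing
within milliseconds. Extracting kinetics from such records requires a
pipeline, and `motrace` provides all of it:

* **Conditioning** — decimation with zero-phase anti-alias filtering, a
  causal exponentially weighted moving average (window 20), and ×100
  downsampling (`preprocess_trace()`).
* **Drift correction** — sub-pixel cross-correlation tracking of fiducial
  markers in video frames, two-marker averaging, local-linear smoothing,
  subtraction, and a Z-drift QC flag (`track_marker()`,
  `combine_and_smooth()`, `correct_drift()`, `qc_z_drift()`).
* **Segmentation** — exact penalized changepoint search for
  constant-velocity segments, fitted by ordinary least squares, run in
  triplicate with jittered penalties to emulate independent human
  segmenters; segments shorter than 10 s are tiled but excluded
  (`segment_record()`, `classify_segments()`, `extract_runs_and_pauses()`).
* **Kinetics** — duration-weighted exponential velocity fits
  (`N_R = floor(duration/10 s)` replication; the MLE is the closed-form
  weighted mean), left-truncated exponential dwell-time fits
  (`tau = mean − 10 s`), two-component mixtures by
  expectation–maximization (tolerance 1e-5 s), a control-derived pause
  threshold (`mu·ln 10` = 0.085 nm/s at the 0.037 nm/s control mean), and
  millisecond jump detection (`fit_exponential_weighted()`,
  `fit_truncated_exponential()`, `fit_double_exponential_em()`,
  `derive_pause_threshold()`, `detect_jumps()`).
* **Statistics** — bootstrap two-sample tests on weighted means
  (H0: mu1 = mu2, recentred null, within-group resampling), 3.5 pN force
  bins centred on zero load, and dataset summaries
  (`bootstrap_mean_test()`, `bin_by_force()`, `summarize_dataset()`).
* **Synthetic data** — a generator with full ground truth: three-state
  Markov motility (forward/backward/paused, exponential dwells,
  occupancies 41/20/39%), exponential speed laws (0.17 / 0.11 nm/s),
  near-linear residual drift (0.037 nm/s scale), Gaussian noise, sigmoidal
  jumps with reversible toggling, and fiducial-marker video rendered from
  the drift path (`simulate_motility_record()`, `simulate_control_record()`,
  `simulate_fiducial_frames()`, `simulate_dataset()`).

Everything is tibble-first: traces, segments, runs and pauses are tibbles,
fitted objects have `tidy()`/`glance()` methods, and `autoplot()` /
`plot_segments()` produce ggplot2 diagnostics.

## Worked example

```r
library(motrace)
library(dplyr)

records <- simulate_dataset(6, sim_config(duration = 140, seed = 42))
result  <- run_pipeline(records, pipeline_config())
result
#> <mot_pipeline> 6 records, 840 s observed; 101 retained segments
#>   occupancy: forward 44.2%, backward 19.2%, paused 36.6%
#>   forward velocity: 0.144 nm/s [0.121, 0.174]
#>   backward velocity: 0.101 nm/s [0.080, 0.129]
```

Each simulated record carries its own instrumental drift, rendered into
fiducial-marker video; `run_pipeline()` tracks the markers, corrects the
drift, removes detected jumps, segments each record three times, classifies
segments against the 0.085 nm/s pause threshold, and fits the velocity and
dwell-time distributions. At this deliberately small size (840 s) the
forward velocity fit, 0.144 [0.121, 0.174] nm/s, brackets loosely; at
larger study sizes the forward-signed class mean concentrates near
0.19 nm/s (the threshold-conditioned moving-speed law diluted by
signed pauses — see the vignette) and the backward class near the
configured 0.11 nm/s.

```r
tidy(result$fits$velocity_forward)
#> # A tibble: 1 × 4
#>   term  estimate conf.low conf.high
#>   <chr>    <dbl>    <dbl>     <dbl>
#> 1 mean     0.144    0.121     0.174

glance(result$fits$run_duration_forward_2exp)
#> # A tibble: 1 × 7
#>   family     logLik n_obs n_effective n_iter converged degenerate
#>   <chr>       <dbl> <int>       <int>  <int> <lgl>     <lgl>
#> 1 trunc_2exp  -129.    33          33     42 TRUE      FALSE

derive_pause_threshold(0.037, quantile = 0.90)
#> [1] 0.08519297
```

The last number is the working pause cutoff: 90% of enzyme-free control
segments (exponential mean speed 0.037 nm/s) move more slowly than
0.085 nm/s, so only faster segments are called motility.

## Package layout

| Directory | Contents |
| --- | --- |
| `R/` | simulation, preprocessing, drift correction, segmentation, kinetics, statistics, io, pipeline |
| `tests/testthat/` | unit, property and end-to-end recovery tests |
| `scripts/acceptance.R` | from-scratch recovery of the headline quantities |
| `vignettes/motility-analysis.Rmd` | the methods vignette: model, parameters, numerics, limitations |
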