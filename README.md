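# glusense

Analysis and simulation toolkit for **genetically encoded glutamate
indicator imaging** (iGluSnFR-family sensors). Fourth-generation
indicators resolve single synaptic vesicle release in vivo; turning such
recordings into numbers requires a stack of specialized estimators, and
`glusense` implements that stack end to end for people building or
benchmarking glutamate-imaging pipelines:

- **Transient kinetics** — spike-triggered averaging of dF/F0 with an
  isolation rule, and nonlinear least-squares fits of the rise/decay
  model
  `dF/F(t) = A (1 − e^(−(t−t0)/τ_rise)) e^(−(t−t0)/τ_decay)`,
  with closed-form amplitude and time-to-peak
  `t* = τ_rise · ln(1 + τ_decay/τ_rise)`; plus autocorrelation-based
  decay estimation (robust log-linear fits over incremental time lags)
  and branch-level minima.
- **Optical minis** — a pixelwise activity statistic (skewness of the
  temporally highpass-filtered series, calibrated so photon shot noise
  gives exactly 1), seeded non-negative factorization for release-site
  extraction, per-site SNR (third-largest peak over a spectral noise
  estimate), per-site decay, and well/variant aggregation.
- **Orientation tuning** — time-resolved and eight-point tuning curves,
  vector-sum preferred orientation and OSI (both published variants),
  HSV pixel maps, and cross-validated pixel-pair tuning covariance
  versus distance with 1/e and 1/e² spread statistics and bootstrap CIs.
- **Spatiotemporal receptive fields** — Toeplitz lagged designs (0–1.4 s)
  with separate ON/OFF predictors, Laplacian-regularized ridge
  regression, 3-fold cross-validated λ, explained variance
  `EV = 1 − Σ(y−ŷ)²/Σ(y−ȳ)²`, a circular-shift permutation test, the
  EV > 0.1 & p < 0.005 responsiveness rule, and 2D-Gaussian subfield
  fits.
- **Mutagenesis GLMs** — categorical models of a 9-site combinatorial
  indicator screen (1,728 genotypes; Poisson-log and Gaussian-log
  families), pairwise epistatic interactions, case-bootstrap CIs,
  genotype-stratified cross-validated variance explained, and
  interaction-magnitude versus residue-distance correlation.
- **Photometry** — polynomial bleach correction plus Gaussian low-cut
  detrending, and peri-event time histograms with 2-s pre-event
  baselines.
- **Synthetic data** — Poisson shot-noise movies over Gaussian synaptic
  footprints, release trains, tuned populations, sparse-noise stimuli
  (2% non-gray at 5 Hz) driving linear RFs, and drifting/bleaching
  photometry traces — all with embedded ground truth, so every estimator
  is tested by parameter recovery. Movies round-trip through a built-in
  multi-page TIFF writer/reader.

## Worked example

Simulate a 30-s optical-mini movie (5 release sites, photon-limited),
detect the sites, and score them:

```r
library(glusense)

cfg <- sim_config(frame_rate = 100, duration = 30, image_shape = c(48, 48),
                  n_sites = 5, footprint_sigma = 1.5,
                  baseline_photon_rate = 20, site_brightness = 60, seed = 1)
kin <- kinetic_params(A = 1.5, tau_rise = 0.002, tau_decay = 0.05)
trains <- lapply(1:5, function(s) simulate_release_train(0.8, 30, seed = s))
movie <- render_movie(cfg, trains, kin)

sites <- detect_sites(movie$frames, frame_rate = 100, footprint_sigma = 1.5)
nrow(sites$centroids)
#> [1] 5

scores <- do.call(rbind, lapply(seq_len(nrow(sites$centroids)), function(s) {
  data.frame(site = s,
             snr = site_snr(sites$traces[s, ], 100)$snr,
             decay_ms = 1000 * site_decay(sites$traces[s, ], 100)$decay_tau)
}))
print(scores, digits = 3)
#>   site  snr decay_ms
#> 1    1 21.0     43.2
#> 2    2 21.8     41.5
#> 3    3 22.8     40.1
#> 4    4 20.3     43.3
#> 5    5 19.2     36.7
```

All five sites are recovered; SNRs around 20 say the third-largest event
at each site stands twenty times above the spectral noise floor, and the
fitted decays scatter below the generating 50 ms because the
factorization traces mix in a little fast photon noise.

Single-AP kinetics at electrophysiology rates (500 Hz): build a noisy
dF/F trace from isolated spikes with a 25.9-ms indicator, then
spike-triggered-average and refit the transient equation:

```r
fr <- 500
spikes <- seq(1, 59, by = 2)
dff <- release_trace(spikes, 60, fr,
                     kinetic_params(A = 0.8, tau_rise = 0.002,
                                    tau_decay = 0.0259))
set.seed(2)
dff <- dff + rnorm(length(dff), 0, 0.02)
sta <- spike_triggered_average(dff, fr, spikes, pre = 0.02, post = 0.2)
fit <- fit_transient(sta$mean, fr, t_start = sta$t[1], t0_known = 0)
round(c(amplitude = fit$amplitude,
        tau_rise_ms = 1000 * fit$params$tau_rise,
        tau_decay_ms = 1000 * fit$params$tau_decay,
        time_to_peak_ms = 1000 * fit$time_to_peak), 2)
#>       amplitude     tau_rise_ms    tau_decay_ms time_to_peak_ms
#>            0.60            1.98           26.05            5.25
```

The fit recovers the generating kinetics (2 ms rise, 25.9 ms decay) from
30 averaged transients; the amplitude (0.60) is the peak of the fitted
curve, smaller than `A = 0.8` because rise and decay overlap.

## Pipelines from the command line

Every stage runs from a JSON config
(`{"stage": ..., "seed": ..., "out_dir": ..., "params": {...}}`):

```sh
Rscript -e 'glusense::cli_main()' simulate_minis  --config sim.json
Rscript -e 'glusense::cli_main()' analyze_minis   --config ana.json
Rscript -e 'glusense::cli_main()' fixtures --out fixtures --seed 1
```

Stages write their artifacts (TIFF movies with JSON sidecars, CSV
tables) plus a `summary_<stage>.json` that records seed and parameter
provenance; identical configs reproduce outputs byte for byte.

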