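---
title: "glusense: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glusense: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`glusense` analyses fluorescence recordings made with surface-displayed
glutamate indicators, where the quantity of interest is the release of
single synaptic vesicles: a few thousand glutamate molecules cleared in
under a millisecond, reported by an indicator whose activation and
deactivation time constants set what a camera or scanner can actually
see. This vignette explains the models behind each module, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what a passing synthetic benchmark does and does not
establish.

# The transient model and its estimators

A single-release fluorescence transient is modelled as

$$\Delta F/F(t) \;=\; A\,\bigl(1 - e^{-(t-t_0)/\tau_{rise}}\bigr)\,
  e^{-(t-t_0)/\tau_{decay}},\qquad t \ge t_0,$$

zero before onset. The model is additive across events (no indicator
saturation — a deliberate non-goal), so a site's ideal trace is its
event train convolved with this kernel (`release_trace()`). Two closed
forms are used throughout and tested against the fits: the peak occurs
at $t^* = \tau_{rise}\ln(1+\tau_{decay}/\tau_{rise})$ after onset, and
the peak value (the *amplitude*, which is what an experimenter reads
off a trace) is strictly smaller than $A$ whenever rise and decay
overlap.

**Fitting (`fit_transient`).** Nonlinear least squares with the time
constants parameterized on a log scale (positivity for free, and the
optimizer cannot step across zero). Initialization is deterministic:
$t_0$ at the last 10%-of-peak crossing before the peak, $\tau_{rise}$ =
2 frames, $\tau_{decay}$ from the 1/e point after the peak, $A$ = peak.
A Nelder–Mead pass handles the non-smooth dependence on $t_0$ (the
model has a kink there); when $t_0$ is free it is profiled with a 1-D
golden-section search around the initializer; a final BFGS polish on
the smooth $(A, \log\tau)$ surface supplies the convergence
diagnostic. Non-convergence is always reported (`converged = FALSE`
with the optimizer state), never silent. On noiseless model-generated
input the recovered decay constant agrees to well under 0.1%; the
acceptance tests require 1%.

**Spike-triggered averaging.** Only isolated spikes enter the average:
no neighbouring spike within 500 ms on either side (default), because a
slow indicator's decay from one action potential contaminates the next
snippet. Zero qualifying spikes is a flagged empty result, not an
error — downstream code decides what to do.

**Decay from autocorrelation.** When no ground-truth event times exist,
the decay constant is estimated from the trace's own temporal structure:
for windows of the recording, the autocorrelation at incremental lags is
fitted on a log scale with a straight line, and the window's constant is
$|1/\text{slope}|$. Choices made here, all documented because the method
is sensitive to them: (i) the lag grid stops at the first nonpositive
autocorrelation — beyond it the log is noise; (ii) the line fit is
Huber-weighted IRLS (k = 1.345) with slope significance from a t-test,
and only windows with $p < 0.001$ and negative slope count; (iii) the
trace-level summary defaults to the *minimum* significant window
constant, mirroring the branch-level convention (`branch_decay()`):
bursts and event overlap can only slow the apparent decay, so the
fastest credible estimate is the least biased one. A `"median"` summary
is available. Be aware of the estimator's small-sample bias: the sample
autocorrelation of a strongly correlated series is biased low by a term
of order (integral timescale)/(window length), which steepens the log
slope. At 10-s windows and a 100-ms constant this is a ~5–10%
underestimate; the package's own recovery tests therefore use windows
long relative to the decay (and lags within about one decay constant),
which is also good practice on real data.

**Event detection.** The modified z-score uses the mean and standard
deviation of the 0.5-s window with the *lowest* s.d. anywhere in the
trace, with an 8×sd threshold and one event per contiguous
supra-threshold run. Selecting the minimum-sd window deflates the
baseline sd slightly (an extreme-value effect that grows as the window
shrinks relative to the trace), so z-units are mildly inflated; at
500 Hz (250-sample windows) the inflation is under ~10%. A zero-sd
baseline (e.g. clipped data) raises a degenerate-baseline error.

# Optical minis

**Activity statistic.** The pixelwise statistic behind activity images
is the sample skewness of the temporally highpass-filtered series,
*calibrated to photon shot noise*. For a Poisson series with mean
$\lambda$ passed through a linear filter with impulse response $c$, the
standardized skewness is $\kappa_f/\sqrt{\lambda}$ with
$\kappa_f = \sum c^3 / (\sum c^2)^{3/2}$. The statistic reported is the
ratio of the observed skewness to that shot-noise prediction,
$\hat g_1 \sqrt{\bar F} / \kappa_f$, which has expectation exactly 1 on
shot-noise-only input regardless of brightness — the property that makes
the image interpretable (values above 1 mean positive skewness in
excess of shot noise, i.e. transients). Without the $\kappa_f$ factor
the statistic would be filter-dependent (about +10% for the default
filter, and exactly 0 for a first-difference filter, whose odd-moment
response vanishes). The default highpass subtracts a Gaussian low-pass
with 4 Hz half-amplitude cutoff; half-kernel edges are trimmed before
the moments. Constant or nonpositive-mean pixels return 0 with a
warning.

**Site extraction.** Full constrained-factorization pipelines are out of
scope; `detect_sites()` keeps their contract (localized, non-negative
sources) with a deliberately simple algorithm: seeds are local maxima of
the activity image above `min_activity` (default 2; shot noise sits at
1), each site's spatial support is a disk of radius 3 footprint-σ around
its seed, footprints start as Gaussians and are refined together with
non-negative traces by multiplicative updates (fixed 30 iterations,
deterministic seed-ordered initialization) on the positive part of
$\Delta F$. Ground-truth recovery on well-separated synthetic sites
(≥ 8 px apart, event SNR ≥ 5) is the module's acceptance bar: all sites
found, centroids within 2 px.

**Scoring.** Site SNR is the amplitude of the *third-largest* peak
divided by a spectral noise estimate — robust to one or two outlier
events while still reflecting real event amplitude. The noise estimate
is the white-noise sd implied by the median periodogram level over the
highest-frequency third of the spectrum (median of an exponential is
$\sigma^2\ln 2$, whence the calibration); it is isolated in one
function so it can be swapped. Peaks for SNR are local maxima above
3×noise with 50-ms separation. Decay scoring additionally requires
*prominent* peaks (≥ 25% of the trace maximum) so small decay-phase
bumps cannot veto the isolation rule; isolation is bootstrapped in two
passes (assume 150 ms, fit, redo at 5× the fitted constant), and a
single exponential with offset is fitted to the mean post-peak trace.
Wells aggregate as the median across sites, variants as mean ± SEM of
well medians — exactly two levels, order-invariant.

# Orientation tuning and spatial spread

Tuning follows the standard grating-session conventions: time-resolved
curves are trial means over the 2-s stimulus window; eight-point curves
subtract the mean of the 0.5 s before onset (additive offsets cancel);
orientation statistics live on doubled angles, so 90° and 270° gratings
share an orientation. Both published OSI variants are computed —
resultant length divided by summed responses (normalized, in [0, 1],
the default wherever a saturation channel needs bounding) and the raw
resultant magnitude. Negative eight-point responses are rectified to
zero before vector summation (resultant-vector math assumes nonnegative
magnitudes); the count of rectified entries is reported. All-zero
curves yield an undefined preferred orientation (flagged `NA`) and OSI
0. Pixel maps use hue = orientation/180, saturation = clipped
normalized OSI, value = amplitude normalized to the field-of-view
maximum.

**Cross-validated spread.** The spatial footprint of a synaptic signal
is measured by the covariance of tuning between pixel pairs, computed
*across mutually exclusive trial halves*: pixel A's tuning curve from
one half, pixel B's from the other, averaged over 20 random splits (and
symmetrized over the two assignments). Because the halves share no
trials, noise that is independent across trials cancels in expectation
and the statistic estimates shared-signal covariance — the package's
tests verify it is unbiased where the naive same-trial covariance is
inflated by shared noise. Curves are binned at 1 px, separately for
labeled pixels (top-q of the mean image dilated by 1 px, q = 0.05
default) and background; both covariance and correlation versions are
emitted, with 1/e and 1/e² crossing distances by linear interpolation
(undefined crossings are `NA`, never extrapolated). Recording-level
means take bootstrap CIs (1,000 resamples, percentiles 2.5/97.5), and
two conditions differ when the CI of their crossing-distance difference
excludes zero.

# Spatiotemporal receptive fields

The stimulus is sparse noise: each grid cell independently non-gray
with probability 2% per 5-Hz frame, black/white equiprobable (the
black/white ratio is not stated in the source conventions; 50/50 is
assumed). The design matrix holds the stimulus history at lags 0–1.4 s
on the response sampling grid, sample-and-hold upsampled, with separate
ON (`max(S,0)`) and OFF (`max(-S,0)`) blocks; early rows with
incomplete history are zero-padded, and row *t* never references the
future. The fit minimizes
$\|y - Xw\|^2 + \lambda\|Lw\|^2$ with $L$ a 4-neighbour discrete
Laplacian with replicate boundaries applied per lag and per block —
spatial smoothing only, no temporal penalty. An unpenalized intercept
is handled implicitly by centring (a rank-1 update of $X'X$), which
matters: without it a noiseless linear response cannot reach EV = 1
because the response mean is outside the sparse design's column space.

λ is chosen by 3-fold cross-validation on *contiguous* time blocks
(random folds would leak autocorrelated samples across the train/test
boundary), maximizing fold-mean explained variance, and the final model
is refit on the full recording at the chosen λ. The default grid is
logarithmic, 10 points per decade over 6 decades, centred on
`mean(diag(X'X))`; tests pass explicit grids. Significance comes from a
circular-shift permutation test: the response is circularly rotated
relative to the stimulus (equivalently, the predictor is rotated) by a
uniform random shift at least 5 s in magnitude, preserving
autocorrelation; the p-value is the fraction of null EVs exceeding the
real one, floored at 1/n_shifts so it is never exactly zero. Note the
floor's practical consequence: with the 0.005 responsiveness threshold,
at least 201 shifts are required for *any* site to classify as
responsive; the reference analysis used 1,000. Responsive =
EV > 0.1 *and* p < 0.005. For responsive sites the combined map is
(ON − OFF)/2 — OFF weights sign-flipped so a site suppressed by light
increments reads negative — and the lag slice with the largest absolute
response is fitted with an elliptical 2D Gaussian (moment
initialization, Nelder–Mead least squares; a failed fit is flagged and
the raw slice still returned).

# Mutagenesis GLMs

The combinatorial screen space is nine categorical sites with two or
three states each (wild type plus substitutions), 1,728 genotypes in
all. Metrics are modelled with wild-type-reference one-hot coding;
pairwise epistasis enters as products of non-reference dummies at
distinct sites (63 terms) — products involving a reference level would
be aliased with main effects. Brightness-like metrics (F0, dF/F0) use
the Poisson family with log link; since the responses are continuous
normalized values, the fit is executed as `quasipoisson(log)`, which
shares the Poisson IRLS point estimates while accepting non-integer
data — inference comes from the case bootstrap, not the family's
variance model. Rise/decay times use Gaussian-log; zeros under a log
link are floored at 1e-6 with a warning, and negative dF/F0 values are
clipped to 0 before fitting. Replicate wells stay unaveraged. Rank
deficiency (e.g. a site that never varies) is an error naming the
aliased columns.

Confidence intervals are case-resampling bootstrap (N rows out of N,
percentile 2.5/97.5; failed resamples are redrawn and counted);
significance is "CI excludes zero". Cross-validated variance explained
stratifies folds by genotype — all replicates of a genotype stay
together, otherwise the model would be graded on memorizing genotype
identities. The epistasis claim is reproduced structurally on synthetic
screens (main effects N(0, 0.3); interactions N(0, 0.2) on 10% of
pairs; scaled-Poisson noise at ~50 photons): with interactions present,
the interaction model beats the additive model on held-out EV across
seeds at the full screen scale. Interaction-versus-distance analysis
takes the minimum inter-atom Euclidean distance per site pair and
Pearson-correlates it with |interaction coefficient|; site pairs
without coordinates are excluded with a message.

# Photometry

Bulk photometry drifts (slow optical/physiological trends) and bleaches
(roughly exponential intensity loss). The detrend models bleaching with
a 4th-order polynomial fitted to the raw trace, converts to dF/F
against that baseline, then removes residual slow modulation with a
Gaussian low-cut (half-amplitude cutoff period 180 s, the midpoint of
the conventional 2–4 min range; σ = √(2 ln 2)/(2π f_c)). The order —
polynomial first, then low-cut — is chosen so that a trace that *is* a
4th-order polynomial maps to numerically zero; filtering first would
leave Gaussian edge transients of order 1e-3 and break that exactness.
The cost is that very large transients can tug the polynomial slightly;
with reward-sized transients the distortion is within the documented
±10% amplitude tolerance. Filter attenuation figures (e.g. >90% of a
10-min sinusoid) hold in the trace interior; reflection padding leaves
the usual smoothing transient within ~2 filter σ of the edges. PETHs
subtract each trial's mean over the 2 s before the event ("reward
consumption" is approximated by delivery time — lick detection is out
of scope) and drop events too close to the trace edges, with a count.

# The synthetic world, and what green tests establish

The generator emulates exactly the statistical structure the estimators
assume: Poisson shot noise over a static background (variance = mean,
verified to 5%), diffraction-limited sites as unit-peak isotropic
Gaussian footprints truncated at 4σ, linear superposition of indicator
kernels, optional exponential photobleaching applied to the labeled
(site) component only — the unlabeled background is autofluorescence
and does not bleach, orientation-tuned event rates
$\exp(\kappa[\cos 2(\theta-\theta_{pref})-1])$, sample-and-hold
stimulus alignment with onsets snapped to frames, and polynomial-drift
photometry. Default rates (e.g. baseline 20 photons/frame/px, site
brightness tens of photons/frame, spontaneous minis below 1 event/s,
preferred-stimulus rates of a few events/s) were chosen once as
representative of photon-limited two-photon and widefield recordings
and are stated in the constructors' documentation; no rig noise floor
exists in the source material, so the acceptance tests state their own.

What a green suite establishes: each estimator inverts the generative
model it assumes, at stated tolerances, with calibrated error rates
(permutation validity, bootstrap coverage). What it does not establish:
robustness to motion, scan distortion, indicator saturation near
release sites, overlapping out-of-focus sources, correlated biological
background, or segmentation errors — all explicitly out of scope. The
same caveat applies to the simplified factorization: it is tested by
ground-truth recovery on separated sites, not claimed to match a full
constrained pipeline on dense neuropil.

Seeds: every stochastic entry point takes one; the CLI derives
per-stage child seeds deterministically from a single global seed (kept
below 2³¹), so stages rerun independently and movies reproduce byte for
byte.

# Known limitations

- The autocorrelation decay estimator is consistent but biased low for
  windows short relative to the decay constant (see above); prefer long
  windows and the median summary when events are not bursty.
- The activity statistic's shot-noise calibration assumes independent
  pixel noise; correlated read noise would shift the baseline away
  from 1.
- The STRF solver forms dense normal equations: fine up to a few
  thousand predictors (the tested grids), not engineered for
  full-screen stimulus grids at video rates.
- Gaussian-log GLM fits can fail on resamples with extreme leverage;
  the bootstrap redraws and reports the count rather than silently
  dropping.
- The minimal TIFF I/O intentionally supports only uncompressed
  little-endian grayscale (8/16-bit unsigned, 32-bit float) — enough
  for interchange with standard readers, not a general TIFF library.
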