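---
title: "Estimating neural formant-frequency resolution by cross-validated kernel smoothing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating neural formant-frequency resolution by cross-validated kernel smoothing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(frfres)
```

## The question and the measurement

Vowel identity is carried by formants — the resonance peaks of the vocal
tract's transfer function. A cortical neuron that contributes to vowel
discrimination must respond differently to sounds whose formants differ by
some minimal frequency step; this package estimates that step, the
*formant-frequency resolution*, from trial-by-trial spike counts.

The stimulus set is a grid of two-formant pulse-resonance sounds: a 151 Hz
click train (the glottal-pulse analog) filtered by two cascaded resonators
with center frequencies F1 < F2 drawn from 11 log-spaced positions between
10 and 20 kHz at 0.1-octave steps, giving `choose(11, 2) = 55` formant
pairs. Responses to each pair, presented 15–20 times, are reduced to a
**formant receptive field** (FRF): the mean onset-window (20–100 ms) firing
rate minus the background rate, laid out over the triangular F1 < F2 grid.

The resolution estimate is the width σ (in octaves) of the 2-D Gaussian
kernel that best smooths the FRF in a cross-validation sense. If responses
to stimuli 0.1 octaves apart are statistically interchangeable, averaging
them (large σ) improves prediction of held-out trials; if they genuinely
differ, averaging blurs real structure and prediction degrades. The σ
minimizing cross-validated prediction error therefore measures the scale
below which the site's responses carry no reliable distinction.

## The response model

Analysis and simulation share one response model, a linear–nonlinear–
Poisson (LN-P) description: each site has a deterministic tuning function
r(S) over the stimuli, and the observed count on a trial is a Poisson draw
around (r(S) + background) × window length. The Poisson choice matches the
empirical regime of cortical multi-unit counts, whose trial-to-trial
variance is close to their mean. `make_ground_truth()` constructs r for
several motif families (bumps, diagonal ridges for sites preferring
closely spaced formants, gradients, flat sites, and smoothed noise fields
of known intrinsic width w); `simulate_trials()` applies the Poisson
stage. The smoothed-noise family is the workhorse for validation because
its smoothness scale w is exactly the quantity σ is supposed to recover.

```{r example, fig.width = 6, fig.height = 3.2}
gt <- make_ground_truth("smoothed_noise", params = list(w = 0.1),
                        amplitude = 50, background_rate = 12.5, seed = 8)
tab <- simulate_trials(gt, n_repeats = 15)
frf <- build_frf(tab)
frf
```

## Windows, background, and the trial table

Counts are taken in half-open windows `[20, 100)` ms (onset response) and
`[400, 480)` ms (baseline) after stimulus onset; equal 80 ms durations
make counts and rates interchangeable up to the factor 1/0.08. The
background rate is the *median* of the per-trial baseline rates pooled
over all stimuli and repeats — the median, not the mean, so occasional
spontaneous bursts in the late window do not inflate the estimate.
Background subtraction happens per trial-set: when the data are split for
cross-validation, the training and test halves each compute their own
median, keeping the two halves fully independent.

## Masked smoothing by normalized convolution

The FRF lives on a triangular 55-cell domain (F1 < F2), so plain
convolution with a square Gaussian kernel would mix in undefined cells.
`smooth_frf()` uses normalized (masked) convolution: for every valid cell
the kernel weights over the *valid* cells are renormalized to sum to one,

> out(S) = Σ w(|S−S′|) frf(S′) / Σ w(|S−S′|),  w(d) = exp(−d²/2σ²),

with distances in octave coordinates. This is the only masked scheme that
preserves constant fields exactly and whose large-σ limit is exactly the
kernel-weighted grand mean — properties the tests assert to machine
precision against an independent brute-force pairwise oracle. No kernel
truncation is applied: the grid spans one octave, so the full 55 × 55
weight matrix is evaluated (and, per σ, precomputed once and reused across
all bootstrap iterations).

The kernel weight function is also the key to *interpreting* σ: at
σ = 0.08 a stimulus 0.1 octaves away still contributes
`r round(100 * kernel_weight(0.1, 0.08), 1)`% of the center weight, at
σ = 0.04 only `r round(100 * kernel_weight(0.1, 0.04), 1)`%, and at
σ = 0.02 a negligible
`r signif(1e6 * kernel_weight(0.1, 0.02), 2)` parts per million — which is
why best-σ values below the 0.1-octave stimulus spacing are meaningful:
they are standard deviations of a weighting function, not grid steps.

## Cross-validation and the σ estimate

`estimate_resolution()` scores each σ on a geometric grid
{0.02, 0.04, …, 5.12} octaves by repeated random splitting: per iteration
the repeats of every stimulus are partitioned without replacement into 10
training and 5 test trials, the training FRF is smoothed with σ, and the
mean squared difference to the raw test FRF over the 55 cells is the
prediction error. Defaults are 500 iterations per σ; a 14:1 leave-one-out
split is supported and behaves equivalently. A natural cubic spline
through the nine mean errors as a function of log2 σ is evaluated on a
1000-point dense grid; its argmin (ties resolved to the smallest σ) is
`best_sigma`, so estimates can fall between the sampled widths. The
bootstrap SEM (SD of the per-iteration errors divided by √n_boot) is
reported for plotting but plays no role in selecting the minimum.

```{r cv, fig.width = 5.5, fig.height = 4}
cv <- estimate_resolution(tab, n_boot = 100)
cv
plot(cv)
```

Two design points were genuinely open and are resolved as follows.
*Split reuse:* a fresh random split is drawn for every (σ, iteration)
pair; `share_splits = TRUE` instead reuses one split per iteration across
all σ, a paired design that reduces between-σ noise. The fresh-split
default is retained because the two converge to the same curve and the
default keeps iterations exchangeable. *Spline domain:* the spline is fit
in log2 σ because the σ samples are geometric; fitting in linear σ would
let the three largest samples dominate the curvature.

Degenerate inputs are handled explicitly: a table with no variation at
all (e.g. all counts zero) yields a flat error curve, flagged `flat`, with
`best_sigma` reported at the largest σ — the grand mean is then trivially
the best predictor.

## Inclusion screening

Before estimating σ on real recordings, sites with no stimulus-driven
modulation should be excluded. `inclusion_test()` pools onset counts by
four quadrants of the formant plane — F2 below the middle grid frequency
("bottom left"), F1 above it ("top right"), F1 + F2 above twice it ("top
left"), and the central remainder — and runs a Kruskal–Wallis test of
those four groups against the baseline counts of all trials as a fifth
group. The quadrant thresholds default to the middle center frequency of
the grid, 10 × 2^0.4 ≈ 13.195 kHz (13.2 kHz in round numbers); because
the defining inequalities are strict, stimuli with a formant exactly at
that grid position fall through to the later quadrants rather than
landing in quadrant 1. The test is rank-based, so it is invariant to any
monotone transformation of the counts, and its null false-positive rate
is calibrated at α in the test suite. No multiple-testing correction is
applied across sites.

## What the synthetic generator does and does not show

The generator reproduces the statistical skeleton of the recordings: the
55-stimulus design, 15 repeats, Poisson count noise, a background process,
and (optionally, via `simulate_trace()`) raw voltage traces with biphasic
spike waveforms in band-limited noise for exercising the detection stage
(4th-order Butterworth 200–2000 Hz, applied forward–backward so spike
times do not shift, with a −3.5 SD negative-peak threshold and 1 ms dead
time). It does *not* model adaptation, bursting, across-site noise
correlations, or within-window spike timing structure, so passing tests
validate the estimator's statistical behavior under the stated noise
model — not the biology of any particular cortical field.

Fixture scales were chosen once as plausible for awake-preparation
multi-unit data: background 12.5 Hz (one expected baseline spike per
80 ms window), evoked amplitudes 50 Hz (≈4 : 1 peak-to-background), and
ground-truth widths {0.05, 0.1, 0.2, 0.4} octaves spanning the range from
sharper-than-grid to coarse tuning. Validation problem sizes are 20 sites
per width at 100 bootstrap iterations, and 1000 null simulations for the
inclusion-test calibration.

## Known limitations

* **Recovery is compressive.** The median estimated σ increases
  monotonically in the true field smoothness w, but not on the identity
  line: subsample cross-validation balances this dataset's split noise
  against *this dataset's* realized structure, so very smooth truths at
  high SNR still admit small optimal σ. σ is an operational resolution
  measure, not an unbiased estimate of w.
* **Flat (pure-noise) sites receive dispersed σ.** For a site with no
  tuning at all, the expected error curve is flat-to-decreasing and the
  median best σ is large, but chance spatial autocorrelation in a given
  55-cell noise realization can place the minimum at intermediate σ; the
  natural spline can also dip just left of a sampled minimum after a
  steep descent. Roughly 60–80% of flat sites land at σ ≥ 0.64 octaves,
  not all of them. In practice this is why the inclusion screen runs
  first: σ is only interpreted for sites with demonstrated stimulus
  drive.
* **Bandwidth conventions.** σ is a Gaussian standard deviation, closer
  to a half-bandwidth; `octaves_to_percent()` and `octaves_to_hz()`
  convert octave intervals (e.g. 2σ as a full bandwidth) into percent
  shifts or Hz for comparison with filter-based tuning measures.
* **Stimulus synthesis details.** The resonator bandwidth (default
  200 Hz, pole radius exp(−πBW/fs)) and pure-pole realization are
  conventional choices; the analysis never depends on them because RMS
  calibration removes overall scale and the estimator consumes only
  spike counts. Sound level is handled as a dimensionless RMS target —
  absolute dB SPL is a property of the playback hardware, recorded as
  metadata only.
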