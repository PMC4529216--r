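# frfres

Estimation of neural formant-frequency resolution from cortical spike
trains, by cross-validated Gaussian kernel smoothing of formant receptive
fields.

## The problem

Vowels are identified by their formants — the resonance peaks of the vocal
tract. For auditory-cortex responses to be useful for vowel
discrimination, firing rates must change reliably when a formant moves by
some minimal frequency step. `frfres` estimates that step for a recording
site, from nothing more than per-trial spike counts to a grid of
two-formant sounds.

The experimental design it supports: two-formant pulse-resonance stimuli
(a 151 Hz click train through two cascaded resonators) with formants F1 <
F2 placed on 11 log-spaced frequencies between 10 and 20 kHz at 0.1-octave
steps — 55 formant pairs, each presented 15–20 times. Responses are
reduced to a **formant receptive field** (FRF): the mean onset-window
(20–100 ms) firing rate minus the median background rate (baseline window
400–480 ms), as a function of (F1, F2).

## The estimator

The FRF is smoothed with a 2-D Gaussian kernel of standard deviation σ
octaves using *normalized (masked) convolution* over the triangular
F1 < F2 domain:

    FRF_σ(S) = Σ_S' w(|S−S'|) FRF(S') / Σ_S' w(|S−S'|),
    w(d) = exp(−d² / 2σ²)

Cross-validation selects σ: the 15 repeats of every stimulus are split at
random into 10 training and 5 test trials, the training FRF is smoothed,
and the mean squared prediction error against the raw test FRF is averaged
over 500 random splits for each σ ∈ {0.02, 0.04, …, 5.12} octaves. A
natural cubic spline through the per-σ means (in log2 σ) is minimized on a
dense grid; the minimizing σ — the smallest smoothing scale at which
pooling neighboring stimuli stops helping prediction — is the site's
**resolution estimate**. Small best σ means neighboring formant stimuli
evoke reliably distinct responses; large best σ means only coarse formant
differences are resolved.

The package also provides the surrounding pipeline: stimulus-bank
synthesis with WAV/CSV output, spike detection from raw voltage traces
(zero-phase 200–2000 Hz Butterworth, −3.5 SD negative-peak threshold), a
quadrant-based Kruskal–Wallis inclusion screen, population summaries and
group comparisons, and a linear–nonlinear–Poisson synthetic-data generator
that makes every stage testable without recordings.

## Worked example

Simulate one recording site whose true tuning function is a smooth random
field of intrinsic width 0.1 octaves, then recover its resolution:

```r
library(frfres)

gt  <- make_ground_truth("smoothed_noise", params = list(w = 0.1),
                         amplitude = 50, background_rate = 12.5, seed = 8)
set.seed(8)
tab <- simulate_trials(gt, n_repeats = 15)

frf <- build_frf(tab)
frf
#> FRF map: 55 valid cells on a 11x11 grid; range [-2.50, 52.50] Hz; background 12.50 Hz

inc <- inclusion_test(tab)
sprintf("inclusion p = %.3g -> included: %s", inc$p_value, inc$include)
#> "inclusion p = 2.7e-116 -> included: TRUE"

set.seed(8)
cv <- estimate_resolution(tab, n_boot = 100)
cv
#> CV curve: 9 sigmas in [0.02, 5.12] oct, 100 splits each; best sigma = 0.0749 oct

octaves_to_percent(cv$best_sigma)
#> 5.3
```

The FRF spans −2.5 to 52.5 Hz above background, the inclusion test detects
the stimulus drive overwhelmingly, and the cross-validated best σ of
0.075 octaves says this site resolves formant shifts of about 5% —
consistent with a ground-truth smoothness of 0.1 octaves under Poisson
trial noise. `plot(cv)` shows the error curve, its spline interpolation,
and the selected minimum; `plot(frf)` draws the receptive field.

A whole synthetic population runs through
`run_synthetic(run_config(), n_sites = 20, out_dir = "out")`, which writes
`results.csv` (one scored site per row), `summary.json` (median σ,
fraction of sites in the 0.05–0.2 octave band), and `config.json`. Real
data enter through `run_real("trials.csv", "manifest.csv")` using the same
formats the synthetic path writes.

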