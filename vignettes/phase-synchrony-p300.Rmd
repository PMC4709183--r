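---
title: "Phase-synchrony analysis of P300 speller sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-synchrony analysis of P300 speller sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

A P300 speller flashes the rows and columns of a character matrix while
the user attends one character. The attended row and column ("target"
flashes, 2 of the `n_rows + n_cols` stimuli per block) evoke a P300 — a
positive deflection roughly 300 ms after stimulus onset — while the
remaining flashes do not. Classical decoders score each averaged
stimulus response with single-channel features (peak amplitude, area
under the P300 window). This package implements, alongside those, a
*functional connectivity* feature: the degree to which distant
electrodes phase-lock to each other during target processing.

The synchrony statistic is the across-trial phase-locking value. Each
epoch is band-pass filtered to 1–12 Hz, its instantaneous phase
$\phi_{x,n}(t)$ extracted as the angle of the analytic (Hilbert)
signal, and for every electrode pair $(x, y)$

$$\mathrm{PLV}_{xy}(t) = \frac{1}{T_r}\left|
  \sum_{n=1}^{T_r} e^{\,i(\phi_{x,n}(t) - \phi_{y,n}(t))}\right|,$$

the mean resultant length of the inter-channel phase difference over
the $T_r$ trials of one stimulus. PLV is 1 when the phase relation is
identical on every trial and falls toward the Rayleigh floor
$\sqrt{\pi}/(2\sqrt{T_r})$ for independent phases ($E[\mathrm{PLV}^2] =
1/T_r$ exactly). It is an *across-trial* statistic: on a single trial
it is undefined, which is why trial-count evaluations require $k \ge 2$
and why single-trial decoding is out of scope.

PLV time courses are averaged over a 200–500 ms post-stimulus window
(centred on the P300 latency) to give a symmetric connectivity matrix.
Significance is decided per pair against 200 phase-randomised
surrogates: each surrogate multiplies the positive-frequency spectrum
of every trial and channel by independent uniform phases — preserving
every amplitude spectrum exactly while destroying cross-channel phase
relations — and the whole phase → PLV → window-average pipeline is
re-run. The one-sided empirical p-value uses the add-one rank
convention $p = (1 + \#\{\mathrm{surr} \ge \mathrm{obs}\})/(1 + n)$,
and an edge is kept when $p < \alpha$ with $\alpha = 0.01$. The **edge
count** of the thresholded graph is the decoding feature: the attended
character is predicted as the intersection of the row stimulus and the
column stimulus with the most edges (ties resolved by higher mean PLV,
then lowest index, and flagged).

## Pipeline and parameters

| parameter | default | units | role |
|---|---|---|---|
| band | 1–12 | Hz | zero-phase FIR band-pass (Hamming windowed-sinc, ~3.3 s at 500 Hz for a 1 Hz transition) |
| epoch window | −200…800 | ms | half-open, so 500 Hz gives exactly 500 samples/trial |
| baseline | −200…0 | ms | per-trial, per-channel z-scoring of ERP epochs |
| P300 window | 220–500 | ms | peak-picking and area features (inclusive bounds; 141 samples at 500 Hz) |
| PLV window | 200–500 | ms | connectivity averaging |
| n_surrogates | 200 | — | null resampling depth; `>= 1/alpha - 1` is enforced, and strict rejection needs `> 1/alpha - 1` |
| alpha | 0.01 | — | per-pair edge significance |
| fb, fc | 2, 1 | s², Hz | complex Morlet parameters of the descriptive time–frequency maps |
| ICA ratio | 3 | — | frontal/other mean absolute mixing-weight ratio above which a component is discarded as ocular |
| train fraction | 0.8 | — | character-level train/test split of the SVM evaluation |

Filtering runs on the continuous recording, before epoching, so filter
transients stay outside the epochs, and it is applied zero-phase
(group-delay compensated) so no latency shift corrupts the P300
window. Characters, channels and stimuli are indexed 1-based
throughout, the native R convention. Stimulus ids `1..n_rows` are
rows and `n_rows+1..n_rows+n_cols` are columns.

Peak picking searches for its "lowest negative point" in the
post-stimulus region before the window, `[0, 220)` ms, rather than the
baseline (the baseline is mean-zero by construction after z-scoring);
the minimum is unconstrained, and the result is flagged when it is
positive. The time–frequency maps use the L1-normalised continuous
wavelet transform with the two-parameter complex Morlet
$\psi(t) = (\pi f_b)^{-1/2} e^{2\pi i f_c t} e^{-t^2/f_b}$ and the
scale-to-frequency map $f = f_c/s$; with L1 normalisation a
unit-amplitude tone at an analysis frequency yields power 1/4 at every
frequency, so equal-amplitude tones are directly comparable. The maps
are descriptive output only, not classifier features.

Two analysis choices were genuinely open and are configurable:
surrogate comparison is made on the *window-averaged* PLV (the same
statistic that defines edges), not pointwise in time; and baseline
normalisation of PLV time courses (`normalize_plv()`) is available but
off by default in the edge decision path.

## What the simulator emulates

Real speller recordings are clinical data that cannot ship with a
package, so every downstream stage is validated against a generator
with known ground truth. A simulated session renders the exact flash
schedule (250 ms onset asynchrony, 150 ms flashes, randomized blocks
of `n_rows + n_cols`, 15 blocks per character, 3 s inter-character
gaps) into a continuous 19-channel, 500 Hz recording containing:

* **1/f background noise**, 10 µV sd per channel (flat below 1 Hz), so
  the 1–12 Hz band-pass stage is consequential;
* on **target flashes only**, a P300-like template on Fz/Cz/Pz/P3/P4:
  a +8 µV Gaussian peak at 350 ms (150 ms FWHM) preceded by a −2.8 µV
  negativity at 180 ms, so peak picking has a genuine pre-window
  minimum to find;
* on **target flashes only**, a 10 µV oscillatory burst at 4–7 Hz
  (drawn per trial), Hann-windowed over 100–600 ms post-stimulus. All
  channels in one connected component of `coupling_pairs` share the
  burst's random-walk carrier phase; each channel adds independent
  Gaussian phase jitter (sd 0.2 rad by default), which makes the
  expected PLV of a coupled pair a tractable, monotonically decreasing
  function of the jitter. Channels connected through a component are
  transitively coupled, so the ground-truth edge set is the
  within-component closure; the default coupling set is already a
  clique (P3, P4, O1, O2, Pz, Cz).

The burst support ends at 600 ms deliberately: with a 250 ms onset
asynchrony the 1 s epochs overlap their neighbours, and a burst
stretching to 800 ms would leak phase-consistent signal into the
200–500 ms window of following non-target epochs. Confining the burst
(with a tapering envelope) keeps that leakage below the numerical
floor of the null — the same reason real non-target epochs are not
fully independent of neighbouring targets, but controlled so that
ground truth stays interpretable.

What the generator does **not** emulate: volume conduction and any
head-model forward projection, amplitude non-stationarity across a
session, real ocular/muscle artifact morphology (blink rejection is
exercised with an explicit synthetic mixing matrix instead), and
between-subject variability. Passing tests therefore demonstrate that
the *pipeline* recovers planted structure under realistic noise — not
that clinical effect sizes would match.

## Numerical choices

* Analytic signals are computed with the one-sided-spectrum FFT
  method; phases are wrapped to $(-\pi, \pi]$ (the $-\pi$ branch point
  is mapped to $+\pi$).
* The surrogate loop is compiled (RcppArmadillo + FFTW): one forward
  FFT per graph, then per surrogate a batched inverse FFT through a
  reused FFTW plan. Random spectral phases come from a
  Mersenne-Twister stream seeded from R's RNG (so `set.seed()` governs
  everything) and are drawn from a 2^16-level phase table — a phase
  granularity of ~1e−4 rad, far below any statistical resolution of a
  200-sample null.
* Degenerate inputs fail loudly: all-zero trial/channel signals
  (undefined phase), zero baseline variance, rank-deficient ICA input
  (reported with its condition number), fewer than 2 trials for PLV.
* The SVM decision scores are orientation-fixed on the training split
  before AUC computation; class imbalance (2:9) is handled with
  inverse-frequency class weights.
* EDF export quantises to 16 bits over each channel's observed range;
  round-trip error is bounded by half a quantisation step.

## Problem sizes used by the test and acceptance runs

The structural identities (trial counts, 171 pairs, 500 samples) and
the target/non-target edge-count contrast run on a full-scale session:
19 channels, 500 Hz, 14 characters × 15 repetitions (420 target / 1890
non-target epochs). The stochastic suites — surrogate calibration
(~2000 pair tests), edge recovery (30 target trials, jitter 0.3 rad,
median over seeds), character decoding (14 characters, median over
seeds) and the AUC-versus-trials curve (k = 2…15) — run at 250 Hz.
The 1–12 Hz band sits far below either Nyquist frequency, so the band
content, phase structure and PLV statistics are unchanged; only the
per-epoch sample count differs (250 instead of 500).

## Known limitations

* PLV at the scalp is sensitive to volume conduction (zero-lag
  spreading of one source to two electrodes); lagged measures such as
  the phase-slope index, and source-space connectivity, are outside
  this package's scope.
* The surrogate test is one-sided (synchrony above the null); it does
  not detect *reduced* coupling.
* Edge counts depend on `alpha` and `n_surrogates` jointly; with
  exactly `n = 1/alpha - 1` surrogates the minimum attainable p equals
  `alpha` and strict rejection is impossible — the validator allows it
  (the rank statistic is well defined) but decoding needs
  `n > 1/alpha - 1`, e.g. the default 200 at `alpha = 0.01`.
* xDAWN and SWLDA baselines are intentionally not re-implemented; the
  evaluation harness compares feature sets (peak, area, PLV and their
  combinations) under one common SVM protocol.
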