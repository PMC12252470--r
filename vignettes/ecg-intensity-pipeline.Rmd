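---
title: "Methods: synthetic ECG, conditioning, delineation, HRV features and intensity classification"
author: "wearecg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ECG, conditioning, delineation, HRV features and intensity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wearecg` re-implements, as a tested software chain, the signal path of a
single-lead wearable ECG monitor: synthetic signal generation with known
ground truth, powerline/noise conditioning, derivative-based fiducial
delineation, interval and heart-rate-variability (HRV) feature extraction,
and a small fully connected neural network (FCNN) that classifies exercise
intensity from those features. This vignette is the package's own account
of the models and the numerical choices behind each stage.

## The synthetic ECG model

Real wearable recordings of the kind this pipeline targets are not
publicly deposited, so every downstream stage is developed and tested
against a generator whose ground truth is analytic.

Each beat is the sum of five Gaussian bumps — P, Q, R, S, T — parameterized
by amplitude (mV), center offset relative to the R peak (s) and width
sigma (s). This is the classic Gaussian-wave simplification of ECG
morphology (the same parameterization that underlies dynamical simulators
such as ECGSYN, minus the phase-oscillator dynamics). The default template

| wave | amplitude (mV) | center (s) | sigma (s) |
|------|---------------:|-----------:|----------:|
| P | 0.15 | -0.22 | 0.025 |
| Q | -0.10 | -0.04 | 0.010 |
| R | 1.00 | 0.00 | 0.012 |
| S | -0.15 | 0.04 | 0.010 |
| T | 0.30 | 0.30 | 0.045 |

is a normal resting adult morphology with a clearly dominant R wave. Wave
peaks are the bump centers; onsets and offsets are defined at ±2.5 sigma,
which keeps every ground-truth landmark a closed-form function of the
template. The `q` and `s` ground-truth columns are the QRS onset
(Q center − 2.5 sigma_Q) and offset (S center + 2.5 sigma_S), so the
ground-truth QRS duration of the default template is
0.04 + 0.04 + 2.5 (0.010 + 0.010) = 0.13 s.

RR intervals follow a mean level plus two sinusoidal modulations — one in
the low-frequency band (default 0.095 Hz, the LF band center) and one in
the high-frequency/respiratory band (default 0.275 Hz) — plus white
Gaussian jitter, evaluated at the running beat time. Specs that could
produce RR ≤ 0.2 s (a 300 bpm instantaneous rate) are rejected at
construction: `mean_rr − lf_amp − hf_amp − 5·jitter_sd` must exceed
0.2 s. Noise is added last: a 50 Hz powerline sinusoid, a slow
baseline-wander sinusoid (0.25 Hz) and broadband white noise, each with
zero default amplitude so a zero noise spec reproduces the clean synthesis
bit for bit.

The default sampling rate is 500 Hz, a conventional rate for wearable
single-lead acquisition that resolves the narrow QRS waves with ~6 samples
per Q/S sigma; rates below 200 Hz are refused.

What the generator does *not* emulate: arrhythmia and ectopic beats,
multichannel leads, electrode-motion artifacts with their characteristic
step discontinuities, and morphology change with heart rate (the template
is fixed while RR varies). Tests passing on this material therefore
demonstrate correctness of the algorithms under clean-to-moderately-noisy
sinus rhythm, not robustness to pathological recordings.

## Signal conditioning

Two digital filters model the monitor's conditioning chain.

**Twin-T-derived notch.** The active twin-T RC network (buffered by
op-amps in a feedback loop) realizes, ideally, the second-order notch
`H(s) = (s² + w0²)/(s² + (w0/Q)s + w0²)`. We discretize this analog
prototype with the bilinear transform, prewarping at the notch frequency,
which places the digital zeros exactly on the unit circle at f0: the
measured `|H(50 Hz)|` is ~1e−14, and gain is exactly 1 at DC and Nyquist
by construction. The −3 dB width is approximately `f0/Q`; the default
Q = 10 gives a ~4.7 Hz notch at fs = 500 Hz (bilinear frequency
compression accounts for the ~6% deviation from 5 Hz), narrow enough to
spare the neighbouring ECG content. The physical circuit's component
values are not modelled — only its ideal transfer function.

**FIR low-pass.** A Hamming-windowed sinc with order N = 15 (16 taps) and
50 Hz cutoff, normalized to exactly unit DC gain. The taps are computed
directly rather than through a design wrapper so the DC normalization is
exact (`|Σh − 1| = 0` in double precision). Symmetry gives exactly linear
phase with a group delay of N/2 = 7.5 samples, which `apply_filter`
compensates (rounded to 8 samples, a half-sample = 1 ms residual at
500 Hz) so fiducial timing is preserved. The −6 dB point of a
windowed-sinc design sits at the cutoff; the realized value is −5.8 dB.

**Edge policy.** Records are reflect-padded before filtering and cropped
after, so output length equals input length and boundary transients do
not shift fiducials. The padding length (max of 3 filter lengths and one
second) covers both the FIR support and the notch ringdown, whose time
constant is 2Q/w0 ≈ 64 ms.

One numerical subtlety surfaced in testing: cascading the notch with
itself re-excites the biquad's own ringdown (a repeated-pole `t·e^(−at)`
response), so "filtering twice" only beats "filtering once" after the
transient has decayed — about 2.5 s at these pole locations. The
idempotence test therefore compares steady-state windows.

## Delineation

The delineator follows the derivative-based scheme: first- and
second-order central differences (scaled by fs and fs² to physical
units), wave peaks at zero crossings of the first derivative, wave
polarity confirmed by the sign of the second derivative at the candidate
(negative curvature for upward P/T, positive for downward Q/S), and the R
wave as the raw-signal maximum of each cycle.

Since "each cycle" presupposes R, detection is bootstrapped by adaptive
thresholding: the 5–20 Hz band-passed signal (where QRS energy
concentrates) is compared against 0.5 × a rolling 2 s maximum of its
envelope, candidate runs are reduced to their envelope maxima, refined to
the raw-signal maximum within ±50 ms, and thinned by a 200 ms refractory
rule that keeps the larger raw amplitude. Every threshold is relative, so
detection is invariant to amplitude scaling, and an all-zero record yields
an empty peak list rather than an error.

Search windows relative to R (P in [−0.30, −0.08] s, Q in
[−0.06, −0.005] s, S in [0.005, 0.06] s, T in [0.12, 0.45] s) span normal
adult morphology from rest through moderate exercise heart rates; each
window is additionally clipped at the midpoints to the neighbouring R
peaks. A wave whose best candidate deviates from the local median by less
than 5% of the R deviation is reported absent rather than fabricated; a
beat whose Q or S wave cannot be located is dropped.

Onsets and offsets are placed where the absolute first derivative falls
below 10% of the flank maximum encountered while walking outward from the
peak. On a Gaussian flank this threshold lands at ±2.76 sigma — slightly
outside the generator's ±2.5 sigma ground-truth convention, a documented
systematic of ~0.26 sigma (2–3 ms for the narrow Q/S waves, ~12 ms for the
wide T offset). Peaks carry no such bias. The per-beat intervals follow
directly: RR between consecutive R peaks, PR from P onset to QRS onset,
QRS from QRS onset to offset, QT from QRS onset to T offset. The "ST
interval" has no unambiguous standard definition; here it runs from the
QRS offset to a T-onset proxy obtained by mirroring the T peak about its
offset (`2·t_peak − t_off`), which is the derivative-threshold equivalent
of T onset for a symmetric wave. All index columns are 1-based in memory
(R convention) and 0-based in the CSV exports.

At short RR (< ~0.6 s) the default P window begins to overlap the
preceding T wave, and P detection may lock onto the T tail; the
delineation property tests randomize mean RR over 0.7–1.0 s, the sinus
range the window defaults were designed for. Window parameters are
exposed in `delineation_config` for faster rhythms.

## Features

* **SDNN** is the population standard deviation of the RR series, in ms.
  The population (divide-by-n) form makes the two-point closed-form cases
  exact; at n ≥ 30 the difference from the sample form is < 2%.
* **LF/HF power.** The RR series (in ms) is cubic-spline interpolated to
  a uniform 4 Hz grid, mean-removed, and its PSD estimated by a
  Hann-window Welch averaged periodogram with 120 s segments and 50%
  overlap, scaled as a one-sided density so that the PSD integral equals
  the series variance (Parseval, up to window bias — the packaged test
  asserts agreement within 25% on 5-minute series). Band powers integrate
  the PSD over 0.04–0.15 Hz (LF) and 0.15–0.40 Hz (HF), the conventional
  short-term HRV bands; both are configurable. At least 30 intervals
  spanning 60 s are required — below that the LF band holds fewer than
  two full cycles and the estimate is meaningless.
* **Record band power** uses the same Welch estimator (4 s segments) on
  the voltage trace, e.g. for the 5–20 Hz QRS-energy band whose power
  rises with heart rate.
* **Agreement metrics** between two simultaneous recordings: Pearson r on
  aligned samples plus absolute differences of mean RR and mean PP
  intervals. Mean RR/PP are computed over consecutive-beat differences
  only (gaps from dropped beats are excluded by a 0.5–1.5 × median
  filter).
* **SNR** is defined, in this package, as `20·log10(RMS_QRS/RMS_iso)`:
  RMS over the delineated QRS windows against the isoelectric segments
  between T offset and the next P onset. The isoelectric RMS is estimated
  robustly (scaled MAD, which equals the RMS for Gaussian noise) because
  the Gaussian wave tails extend past the nominal ±2.5 sigma offsets and
  would otherwise register as "noise" even on a noiseless record. Ratios
  above 60 dB are reported as the +80 dB cap ("numerically zero noise").
* The **feature vector** is the record-level median of the five intervals
  plus SDNN, LF and HF, in the fixed order (rr, pr, st, qrs, qt, sdnn,
  lf, hf); z-score normalization parameters are computed on training data
  only and stored with the model.

## The intensity classifier

The classifier is a fully connected network 8 → 32 → 16 → K with ReLU
activations, inverted dropout (p = 0.3) after each hidden layer during
training, and a softmax output, trained by Adam (learning rate 1e−3,
batch 32) on cross-entropy. After every epoch the validation loss is
evaluated with dropout disabled; an improvement is a decrease of more
than 1e−6 (absolute), and training halts at the 200-epoch cap or once the
loss has not improved for 10 consecutive epochs, returning the
best-epoch weights. Hidden widths, optimizer settings and the 60/20/20
stratified split are this package's choices (configurable); the
two-hidden-layer shape, dropout rate, patience and epoch cap are the
protocol the pipeline is built to reproduce. All randomness — weight
initialization, shuffling, dropout masks, the data generator — is seeded,
so the train/evaluate path is bit-reproducible.

Feature importance is permutation importance (mean accuracy drop over
seeded shuffles of one column at a time): it is model-agnostic,
deterministic under seed, and splits credit between correlated copies of
a feature, which the test suite checks explicitly.

### The synthetic intensity dataset

The training surface is a class-conditional Gaussian dataset over the 8
features: five intensity levels (rest plus four cycling checkpoints),
200 samples per class, root seed 42. The per-class means follow exercise
physiology — RR falls from 0.85 s to 0.53 s (HR 71 → 113 bpm), PR/ST/QT
shorten with rate, QRS stays nearly constant, and the HRV features
collapse with vagal withdrawal (SDNN 60 → 20 ms, LF 900 → 300 ms²,
HF 800 → 200 ms²). The standard deviations (0.025 s RR, 5 ms SDNN,
60 ms² LF/HF, …) put adjacent classes at a combined Mahalanobis
separation of ~5.4, i.e. a Bayes error of a few tenths of a percent —
separable but not trivially so, which is what a feature set this
informative looks like on real within-subject exercise data. These
distribution parameters are the study conditions of the packaged
experiments and are deliberately not adjusted elsewhere.

Because the features are drawn directly from Gaussians rather than
extracted from simulated recordings per class, the classifier experiments
isolate the model/training protocol from delineation error; the pipeline
(`run_pipeline`) demonstrates the full record-to-label path.

## Problem sizes

The packaged tests and scripts use desk-scale problems chosen to make
every statistical assertion stable under its stated tolerance: 5-minute
RR series for spectral oracles, 50 randomized templates for the
delineation property test, 96 s records for the end-to-end pipeline, and
the 1000-sample intensity dataset for training runs (a couple of seconds
per fit).

## Known limitations

* The Gaussian-bump morphology has symmetric waves; asymmetric T waves
  and biphasic P waves are not represented, and the T-onset proxy relies
  on that symmetry.
* The delineator assumes a positive dominant R deflection by default
  (configurable polarity map); it does not auto-detect lead inversion.
* The notch/FIR pair models the monitor's ideal transfer functions, not
  component tolerances or op-amp non-idealities.
* HRV band powers from ~100 s records carry large estimator variance in
  the LF band; the defaults follow short-term-HRV practice but 5-minute
  records are the intended regime.
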