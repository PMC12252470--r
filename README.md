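# wearecg

Single-lead wearable ECG analysis in R: synthetic ECG generation with
analytic ground truth, digital signal conditioning (twin-T-derived 50 Hz
notch + Hamming-window FIR low-pass), derivative-based fiducial
delineation, interval/HRV feature extraction, and a fully connected
neural-network (FCNN) classifier of exercise intensity.

## The problem

Wearable single-lead monitors acquire ECG under powerline interference,
baseline wander and broadband noise, then reduce each recording to a
handful of physiologically meaningful numbers: the per-beat intervals
(RR, PR, ST, QRS, QT) and heart-rate-variability summaries (SDNN and the
LF/HF spectral powers of the RR series). Those eight features are enough
to grade exercise intensity with a small dense network. This package
implements that whole chain as composable, seeded, unit-tested functions,
developed against a synthetic generator so that every stage can be scored
against exact ground truth without any external recordings.

The core pieces, in the field's standard notation:

* **Notch**: the analog twin-T prototype
  `H(s) = (s² + ω₀²)/(s² + (ω₀/Q)s + ω₀²)` discretized by the
  prewarped bilinear transform → exact zeros at 50 Hz, unity gain at DC
  and Nyquist, −3 dB width ≈ f₀/Q.
* **FIR**: order N = 15 Hamming-windowed sinc, cutoff 50 Hz, unit DC
  gain, linear phase (group delay N/2 compensated before delineation).
* **Delineation**: wave peaks at zero crossings of x′(t), polarity from
  the sign of x″(t), R as the per-cycle raw maximum bootstrapped by
  adaptive thresholding of the 5–20 Hz band; onsets/offsets at the 10%
  point of the flank |x′|.
* **HRV**: SDNN = population SD of RR (ms); LF/HF = Welch PSD integrals
  of the 4 Hz-resampled RR series over 0.04–0.15 / 0.15–0.40 Hz (ms²).
* **Classifier**: FCNN 8 → 32 → 16 → K, ReLU, dropout p = 0.3, Adam on
  cross-entropy, early stopping with patience 10 under a 200-epoch cap,
  best-epoch weights returned.

## Worked example

The `analysis/` directory holds the numbered workflow (simulate →
condition → delineate → features → train). Running it end to end:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_condition.R
Rscript analysis/03_delineate.R
Rscript analysis/04_features.R
Rscript analysis/05_train_model.R
```

prints, step by step (output of an actual run):

```
simulated 97 s of ECG at 500 Hz: 121 beats, mean HR 75.0 bpm
intensity dataset: 1000 samples, 5 classes, split 600/200/200
notch: |H(50 Hz)| = 5.80e-15, -3 dB width 4.67 Hz (f0/Q = 5)
FIR: 16 taps, DC gain 1.000000000, gain at cutoff -5.82 dB
50 Hz line attenuated 57.5 dB; 1-40 Hz band changed 0.16 dB
R peaks: 121 detected / 121 true; sensitivity 1.000, PPV 1.000
median |error|: R 0.0 ms, P 4.0 ms, T 4.0 ms
interval medians (s): RR 0.800, PR 0.206, ST 0.148, QRS 0.138, QT 0.456
SDNN 19.5 ms, LF 201.6 ms^2, HF 135.5 ms^2 (LF/HF 1.49)
held-out accuracy: 98.5% on 200 samples
```

Reading these numbers: the simulated 0.1 mV powerline line is pushed
~57 dB below the ECG while the 1–40 Hz cardiac band moves by only
0.16 dB; every one of the 121 R peaks is recovered exactly, and the P/T
peaks to within 4 ms of the generator's ground truth; the recovered
median RR (0.800 s) matches the generator's 75 bpm specification; and the
FCNN grades the five intensity levels at 98.5% held-out accuracy, with
the confusion concentrated between adjacent intensity levels and the
permutation importances dominated by RR and the HRV features.

The same chain is available as one call on a config object:

```r
library(wearecg)
out <- run_pipeline(pipeline_config(n_beats = 120, seed = 42L), "run1")
out$features
```

## Layout

* `R/` — package code: `synth` (generator), `conditioning` (filters),
  `delineate`, `features`, `model` (FCNN), `pipeline`/`record` (I/O,
  config, end-to-end driver).
* `analysis/` — the numbered workflow scripts shown above; artifacts land
  in `results/`.
* `vignettes/ecg-intensity-pipeline.Rmd` — the methods vignette: model
  assumptions, parameter defaults and units, numerical choices, known
  limitations.
* `tests/testthat/` — the unit/property/acceptance suite.
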