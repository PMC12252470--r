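#!/usr/bin/env Rscript
# Step 1: generate the synthetic study material.
#   - a 96 s single-lead ECG at 500 Hz with LF/HF-modulated RR series and
#     realistic contamination (0.1 mV 50 Hz powerline, 0.05 mV baseline
#     wander, 0.02 mV broadband), plus its per-beat ground truth;
#   - the default 5-class exercise-intensity feature dataset
#     (200 samples/class, root seed 42).

suppressPackageStartupMessages(library(wearecg))
dir.create("results", showWarnings = FALSE)

sim <- generate_ecg(
  template = beat_template(),
  rr_spec = rr_series_spec(120, mean_rr = 0.8, lf_amp = 0.02,
                           hf_amp = 0.015, jitter_sd = 0.01, seed = 42L),
  noise = noise_spec(powerline_amp = 0.1, baseline_amp = 0.05,
                     broadband_sd = 0.02, seed = 43L),
  fs = 500
)
write_record(sim$record, "results/ecg_raw.csv")
write_record(sim$clean, "results/ecg_clean.csv")
write_ground_truth(sim$truth, "results/ground_truth.csv")
write_record_wfdb(sim$record, "results/ecg_raw")

cat(sprintf("simulated %.0f s of ECG at %g Hz: %d beats, mean HR %.1f bpm\n",
            duration(sim$record), sim$record$fs,
            nrow(sim$truth$fiducials), 60 / mean(sim$truth$rr)))

ds <- generate_intensity_dataset(intensity_class_spec(seed = 42L))
write_dataset(ds, "results/intensity_dataset.csv")
cat(sprintf("intensity dataset: %d samples, %d classes, split %s\n",
            nrow(ds$x), ds$spec$n_classes,
            paste(table(ds$split), collapse = "/")))
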