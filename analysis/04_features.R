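#!/usr/bin/env Rscript
# Step 4: HRV metrics, band power, SNR and the assembled feature vector
# for the filtered record of steps 1-3.

suppressPackageStartupMessages(library(wearecg))

filtered <- read_record("results/ecg_filtered.csv")
fid_disk <- utils::read.csv("results/fiducials.csv")
idx_cols <- setdiff(names(fid_disk), "beat")
fid_disk[idx_cols] <- lapply(fid_disk[idx_cols], function(v) v + 1L)
fid <- structure(fid_disk, fs = filtered$fs,
                 class = c("fiducial_set", "data.frame"))

iv <- utils::read.csv("results/intervals.csv")
fs <- filtered$fs
hrv <- hrv_metrics(fid$r[-1] / fs, diff(fid$r) / fs)
fv <- build_feature_vector(iv, hrv)
utils::write.csv(as.data.frame(t(fv)), "results/features.csv",
                 row.names = FALSE, quote = FALSE)
write_spectrum(filtered, "results/record_spectrum.csv")

snr <- estimate_snr(filtered, fid)
cat(sprintf("SDNN %.1f ms, LF %.1f ms^2, HF %.1f ms^2 (LF/HF %.2f)\n",
            hrv$sdnn, hrv$lf_power, hrv$hf_power, hrv$lf_hf_ratio))
cat(sprintf("5-20 Hz band power %.4f mV^2; record SNR %.1f dB\n",
            signal_band_power(filtered, 5, 20), snr))
cat("feature vector (rr, pr, st, qrs, qt, sdnn, lf, hf):\n")
print(round(fv, 4))
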