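#!/usr/bin/env Rscript
# Step 2: digital signal conditioning.
# Designs the twin-T-derived 50 Hz notch (Q = 10) and the order-15
# Hamming FIR low-pass (50 Hz cutoff), reports their frequency responses,
# and filters the raw record from step 1. Verifies on the way that the
# 50 Hz line is suppressed while the 1-40 Hz ECG band is untouched.

suppressPackageStartupMessages(library(wearecg))

raw <- read_record("results/ecg_raw.csv")
notch <- design_twin_t_notch(50, 10, raw$fs)
fir <- design_fir_lowpass(15, 50, raw$fs, "hamming")

utils::write.csv(freq_response_table(notch), "results/notch_response.csv",
                 row.names = FALSE, quote = FALSE)
utils::write.csv(freq_response_table(fir), "results/fir_response.csv",
                 row.names = FALSE, quote = FALSE)
write_filter_coefficients(fir, "results/fir_taps.csv")

filtered <- apply_filter(apply_filter(raw, notch), fir)
write_record(filtered, "results/ecg_filtered.csv")

line_before <- signal_band_power(raw, 49.5, 50.5)
line_after <- signal_band_power(filtered, 49.5, 50.5)
band_before <- signal_band_power(raw, 1, 40)
band_after <- signal_band_power(filtered, 1, 40)
cat(sprintf("notch: |H(50 Hz)| = %.2e, -3 dB width %.2f Hz (f0/Q = 5)\n",
            abs(freq_response(notch, 50)), {
              f <- seq(40, 60, by = 0.01)
              H <- abs(freq_response(notch, f))
              diff(range(f[H <= 1 / sqrt(2)]))
            }))
cat(sprintf("FIR: %d taps, DC gain %.9f, gain at cutoff %.2f dB\n",
            length(fir$b), sum(fir$b),
            20 * log10(abs(freq_response(fir, 50)))))
cat(sprintf("50 Hz line attenuated %.1f dB; 1-40 Hz band changed %.2f dB\n",
            10 * log10(line_before / line_after),
            10 * log10(band_before / band_after)))
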