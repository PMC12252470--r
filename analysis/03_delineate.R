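#!/usr/bin/env Rscript
# Step 3: derivative-based delineation of the filtered record and accuracy
# against the generator's ground truth.

suppressPackageStartupMessages(library(wearecg))

filtered <- read_record("results/ecg_filtered.csv")
truth <- utils::read.csv("results/ground_truth.csv")

r_peaks <- detect_r_peaks(filtered)
fid <- locate_fiducials(filtered, r_peaks)
write_fiducials(fid, "results/fiducials.csv")
iv <- compute_intervals(fid)
write_intervals(iv, "results/intervals.csv")

fs <- filtered$fs
truth_r <- truth$r + 1  # ground truth is 0-based on disk
win <- 0.05 * fs
sens <- mean(vapply(truth_r, function(r) any(abs(r_peaks - r) <= win),
                    logical(1)))
ppv <- mean(vapply(r_peaks, function(p) any(abs(truth_r - p) <= win),
                   logical(1)))
match_err <- function(det, tru) {
  stats::median(vapply(det, function(d) min(abs(tru - d)), numeric(1))) /
    fs * 1000
}
cat(sprintf("R peaks: %d detected / %d true; sensitivity %.3f, PPV %.3f\n",
            length(r_peaks), length(truth_r), sens, ppv))
cat(sprintf("median |error|: R %.1f ms, P %.1f ms, T %.1f ms\n",
            match_err(r_peaks, truth_r),
            match_err(fid$p_peak[!is.na(fid$p_peak)], truth$p_peak + 1),
            match_err(fid$t_peak[!is.na(fid$t_peak)], truth$t_peak + 1)))
cat(sprintf("interval medians (s): RR %.3f, PR %.3f, ST %.3f, QRS %.3f, QT %.3f\n",
            stats::median(iv$rr_s, na.rm = TRUE),
            stats::median(iv$pr_s, na.rm = TRUE),
            stats::median(iv$st_s, na.rm = TRUE),
            stats::median(iv$qrs_s, na.rm = TRUE),
            stats::median(iv$qt_s, na.rm = TRUE)))
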