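#' SDNN: standard deviation of normal-to-normal intervals
#'
#' Population (divide-by-n) standard deviation of the RR series, in
#' milliseconds. The population form makes small closed-form cases exact;
#' at study scale the sample/population difference is negligible.
#'
#' @param rr_s RR intervals in seconds (>= 2 values).
#' @return SDNN in ms.
#' @examples
#' sdnn(rep(c(0.8, 1.0), 10))  # 100 ms exactly
#' @export
sdnn <- function(rr_s) {
  rr_s <- rr_s[!is.na(rr_s)]
  if (length(rr_s) < 2) stop("need at least 2 RR intervals", call. = FALSE)
  sqrt(mean((rr_s - mean(rr_s))^2)) * 1000
}

# Hann-window Welch averaged periodogram, one-sided density scaling:
# sum(psd) * df == variance of the (windowed) input, up to window bias.
welch_psd <- function(x, fs, segment_s = NULL, overlap = 0.5) {
  n <- length(x)
  nseg <- if (is.null(segment_s)) n else min(n, max(16, round(segment_s * fs)))
  step <- max(1, floor(nseg * (1 - overlap)))
  starts <- seq(1, n - nseg + 1, by = step)
  k <- 0:(nseg - 1)
  w <- 0.5 - 0.5 * cos(2 * pi * k / (nseg - 1))
  u <- sum(w^2)
  nf <- floor(nseg / 2) + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    p <- (Mod(X)^2) / (fs * u)
    # one-sided: double everything except DC (and Nyquist when nseg even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  psd <- acc / length(starts)
  freq <- (seq_len(nf) - 1) * fs / nseg
  list(freq = freq, psd = psd, df = fs / nseg)
}

band_power_from_psd <- function(sp, band) {
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  sum(sp$psd[sel]) * sp$df
}

#' HRV spectral powers (LF/HF)
#'
#' The RR series (ms) is interpolated to a uniform grid by a cubic spline
#' of RR against beat time, detrended per segment, and its power spectral
#' density estimated with a Hann-window Welch averaged periodogram
#' (120 s segments, 50% overlap). Band powers are the PSD integral over
#' the LF and HF bands; units ms^2.
#'
#' @param beat_times Times of the beats ending each interval (s); any
#'   constant shift of all times leaves the result unchanged.
#' @param rr_s RR intervals (s), same length as `beat_times`.
#' @param resample_hz Uniform resampling rate; default 4 Hz.
#' @param band_lf,band_hf Band edges in Hz; defaults 0.04-0.15 and
#'   0.15-0.40, the conventional short-term HRV bands.
#' @param segment_s Welch segment length (s), capped at the record span.
#' @return A list `lf_power`, `hf_power`, `lf_hf_ratio` (NA when HF is 0),
#'   `total_power` (ms^2), plus the `freq`/`psd` table.
#' @export
hrv_spectrum <- function(beat_times, rr_s, resample_hz = 4,
                         band_lf = c(0.04, 0.15), band_hf = c(0.15, 0.40),
                         segment_s = 120) {
  ok <- !is.na(rr_s) & !is.na(beat_times)
  beat_times <- beat_times[ok]; rr_s <- rr_s[ok]
  if (length(rr_s) < 30 || diff(range(beat_times)) < 60) {
    stop("need >= 30 intervals spanning >= 60 s for LF/HF estimation",
         call. = FALSE)
  }
  span <- diff(range(beat_times))
  grid <- seq(min(beat_times), max(beat_times), by = 1 / resample_hz)
  rr_ms <- stats::spline(beat_times, rr_s * 1000, xout = grid,
                         method = "fmm")$y
  sp <- welch_psd(rr_ms - mean(rr_ms), fs = resample_hz,
                  segment_s = min(segment_s, span), overlap = 0.5)
  lf <- band_power_from_psd(sp, band_lf)
  hf <- band_power_from_psd(sp, band_hf)
  list(lf_power = lf, hf_power = hf,
       lf_hf_ratio = if (hf > 0) lf / hf else NA_real_,
       total_power = sum(sp$psd) * sp$df,
       freq = sp$freq, psd = sp$psd)
}

#' Combined HRV metrics
#'
#' @inheritParams hrv_spectrum
#' @return List `sdnn` (ms), `lf_power`, `hf_power` (ms^2), `lf_hf_ratio`.
#' @export
hrv_metrics <- function(beat_times, rr_s, ...) {
  sp <- hrv_spectrum(beat_times, rr_s, ...)
  list(sdnn = sdnn(rr_s), lf_power = sp$lf_power, hf_power = sp$hf_power,
       lf_hf_ratio = sp$lf_hf_ratio)
}

#' Band power of an ECG record
#'
#' PSD integral over `[f_lo, f_hi]` via the Welch estimator (Hann window,
#' 4 s segments, 50% overlap). Units mV^2.
#'
#' @param record An `ecg_record` of duration >= 4 s.
#' @param f_lo,f_hi Band edges in Hz, `f_hi > f_lo`.
#' @param segment_s Welch segment length (s).
#' @return Band power in mV^2.
#' @export
signal_band_power <- function(record, f_lo, f_hi, segment_s = 4) {
  stopifnot(inherits(record, "ecg_record"))
  if (f_hi <= f_lo) stop("f_hi must exceed f_lo", call. = FALSE)
  if (duration(record) < 4) stop("record must be >= 4 s", call. = FALSE)
  sp <- welch_psd(record$values - mean(record$values), record$fs,
                  segment_s = min(segment_s, duration(record)))
  band_power_from_psd(sp, c(f_lo, f_hi))
}

#' Record spectrum export
#'
#' @param record An `ecg_record`.
#' @param path Output CSV path; columns `freq_hz,psd`.
#' @param segment_s Welch segment length (s).
#' @export
write_spectrum <- function(record, path, segment_s = 4) {
  sp <- welch_psd(record$values - mean(record$values), record$fs,
                  segment_s = min(segment_s, duration(record)))
  utils::write.csv(data.frame(freq_hz = sp$freq, psd = sp$psd), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Agreement metrics between two simultaneous recordings
#'
#' Pearson correlation of the aligned samples, plus the absolute
#' difference of the mean RR interval and of the mean PP interval (from
#' P-peak indices) between the two delineations.
#'
#' @param record_a,record_b Equal-length `ecg_record`s.
#' @param fiducials_a,fiducials_b `fiducial_set`s with >= 2 beats each.
#' @return List `pearson_r`, `mean_rr_diff` (s), `mean_pp_diff` (s, NA if
#'   either recording lacks two located P waves).
#' @export
agreement_metrics <- function(record_a, record_b, fiducials_a, fiducials_b) {
  stopifnot(inherits(record_a, "ecg_record"), inherits(record_b, "ecg_record"))
  if (length(record_a$values) != length(record_b$values)) {
    stop("records must have equal length for Pearson correlation",
         call. = FALSE)
  }
  if (nrow(fiducials_a) < 2 || nrow(fiducials_b) < 2) {
    stop("need >= 2 beats in each fiducial set", call. = FALSE)
  }
  r <- stats::cor(record_a$values, record_b$values)
  mean_rr <- function(fid, fs) {
    d <- diff(fid$r)
    # a dropped beat leaves a double-length gap; keep consecutive diffs only
    d <- d[d >= 0.5 * stats::median(d) & d <= 1.5 * stats::median(d)]
    mean(d) / fs
  }
  mean_pp <- function(fid, fs) {
    p <- fid$p_peak[!is.na(fid$p_peak)]
    if (length(p) < 2) return(NA_real_)
    d <- diff(p)
    d <- d[d >= 0.5 * stats::median(d) & d <= 1.5 * stats::median(d)]
    mean(d) / fs
  }
  fa <- as.data.frame(fiducials_a); fb <- as.data.frame(fiducials_b)
  list(
    pearson_r = r,
    mean_rr_diff = abs(mean_rr(fa, record_a$fs) - mean_rr(fb, record_b$fs)),
    mean_pp_diff = abs(mean_pp(fa, record_a$fs) - mean_pp(fb, record_b$fs))
  )
}

#' Estimate the signal-to-noise ratio of a delineated record
#'
#' `20 log10(RMS_QRS / RMS_iso)`: RMS over all samples inside QRS windows
#' `[q, s]` against RMS over isoelectric windows between each T offset and
#' the next P onset (both measured about the isoelectric mean level). The
#' isoelectric RMS is estimated robustly (scaled median absolute
#' deviation, which coincides with the RMS for Gaussian noise) so that the
#' slow T/P-wave tails extending past the nominal offsets do not register
#' as noise. Ratios above 60 dB are treated as numerically zero noise and
#' reported as the +80 dB cap.
#'
#' @param record An `ecg_record`.
#' @param fiducials A `fiducial_set` with >= 3 delineated beats.
#' @return SNR in dB.
#' @export
estimate_snr <- function(record, fiducials) {
  f <- as.data.frame(fiducials)
  if (nrow(f) < 3) stop("need >= 3 delineated beats", call. = FALSE)
  x <- record$values
  qrs_idx <- unlist(mapply(function(a, b) a:b, f$q, f$s, SIMPLIFY = FALSE))
  iso_idx <- integer(0)
  for (i in seq_len(nrow(f) - 1)) {
    a <- f$t_off[i]; b <- f$p_on[i + 1]
    if (is.na(a) || is.na(b) || b <= a + 1) next
    iso_idx <- c(iso_idx, (a + 1):(b - 1))
  }
  if (!length(iso_idx)) stop("no isoelectric samples between beats",
                             call. = FALSE)
  iso_mu <- stats::median(x[iso_idx])
  s_rms <- sqrt(mean((x[qrs_idx] - iso_mu)^2))
  n_rms <- stats::mad(x[iso_idx])  # robust RMS; = sd for Gaussian noise
  if (n_rms <= s_rms * 1e-3) return(80)
  20 * log10(s_rms / n_rms)
}

#' Assemble the 8-feature classification vector
#'
#' Record-level medians of the five per-beat intervals (RR, PR, ST, QRS,
#' QT, in s) followed by SDNN (ms) and LF/HF powers (ms^2), in the fixed
#' canonical order used throughout the package.
#'
#' @param intervals Data frame from [compute_intervals()] with >= 5 valid
#'   beats.
#' @param hrv List from [hrv_metrics()] (fields `sdnn`, `lf_power`,
#'   `hf_power`).
#' @return Named numeric vector `rr, pr, st, qrs, qt, sdnn, lf, hf`.
#' @export
build_feature_vector <- function(intervals, hrv) {
  valid <- stats::complete.cases(intervals[c("pr_s", "st_s", "qrs_s", "qt_s")])
  if (sum(valid) < 5) stop("need >= 5 beats with complete intervals",
                           call. = FALSE)
  med <- function(v) stats::median(v, na.rm = TRUE)
  out <- c(rr = med(intervals$rr_s), pr = med(intervals$pr_s),
           st = med(intervals$st_s), qrs = med(intervals$qrs_s),
           qt = med(intervals$qt_s), sdnn = hrv$sdnn,
           lf = hrv$lf_power, hf = hrv$hf_power)
  if (any(!is.finite(out))) stop("non-finite feature value", call. = FALSE)
  out
}
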