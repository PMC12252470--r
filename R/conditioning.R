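#' Filter specification
#'
#' Holds transfer-function coefficients plus the design parameters, so a
#' design can be re-created or exported. `b`/`a` follow the usual DSP
#' convention (numerator/denominator in powers of z^-1, `a[1] = 1`).
#'
#' @keywords internal
filter_spec <- function(kind, b, a, fs, params, group_delay = 0) {
  structure(list(kind = kind, b = b, a = a, fs = fs, params = params,
                 group_delay = group_delay),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s @ fs=%g Hz; %d/%d coefficients\n",
              x$kind, x$fs, length(x$b), length(x$a)))
  invisible(x)
}

#' Design a twin-T-derived digital notch filter
#'
#' Models the ideal transfer function of an active twin-T notch (the RC
#' twin-T network buffered by op-amps in a feedback loop): the analog
#' prototype `H(s) = (s^2 + w0^2) / (s^2 + (w0/Q) s + w0^2)` discretized by
#' the bilinear transform with frequency prewarping at `f0`, which places
#' the transfer-function zeros exactly on the unit circle at the notch
#' frequency. Gain is exactly 1 at DC and Nyquist; the -3 dB width is
#' approximately `f0 / q`.
#'
#' @param f0 Notch frequency in Hz (0 < f0 < fs/2); default 50 Hz powerline.
#' @param q Quality factor (> 0); default 10 gives a ~5 Hz notch that
#'   spares neighbouring ECG content.
#' @param fs Sampling rate in Hz.
#' @return A `filter_spec` (biquad, `group_delay = 0`).
#' @export
design_twin_t_notch <- function(f0 = 50, q = 10, fs = 500) {
  stopifnot(f0 > 0, q > 0, fs > 0)
  if (f0 >= fs / 2) {
    stop(sprintf("notch frequency %g Hz violates Nyquist (fs/2 = %g Hz)",
                 f0, fs / 2), call. = FALSE)
  }
  w0 <- tan(pi * f0 / fs)  # prewarped analog frequency (bilinear scale 1)
  b <- c(1 + w0^2, 2 * (w0^2 - 1), 1 + w0^2)
  a <- c(1 + w0 / q + w0^2, 2 * (w0^2 - 1), 1 - w0 / q + w0^2)
  b <- b / a[1]
  a <- a / a[1]
  filter_spec("biquad-notch", b, a, fs,
              params = list(f0 = f0, q = q), group_delay = 0)
}

#' Design a Hamming-window FIR low-pass filter
#'
#' Windowed-sinc design: `order + 1` taps, symmetric (exactly linear
#' phase), normalized to unit DC gain. The default order 15 with a 50 Hz
#' cutoff at fs = 500 Hz mirrors the digital smoothing stage of the
#' wearable system this package models.
#'
#' @param order Filter order N (taps = N + 1); >= 2.
#' @param cutoff Cutoff frequency in Hz (0 < cutoff < fs/2); the -6 dB
#'   point of the design.
#' @param fs Sampling rate in Hz.
#' @param window `"hamming"` (default), `"hann"` or `"rectangular"`.
#' @return A `filter_spec` with `group_delay = order / 2` samples.
#' @export
design_fir_lowpass <- function(order = 15, cutoff = 50, fs = 500,
                               window = c("hamming", "hann", "rectangular")) {
  window <- match.arg(window)
  stopifnot(order >= 2, cutoff > 0, fs > 0)
  if (cutoff >= fs / 2) {
    stop(sprintf("cutoff %g Hz violates Nyquist (fs/2 = %g Hz)",
                 cutoff, fs / 2), call. = FALSE)
  }
  n <- order + 1L
  m <- (0:order) - order / 2
  fc <- cutoff / fs  # cycles per sample
  h <- 2 * fc * sinc(2 * fc * m)
  k <- 0:order
  w <- switch(window,
    hamming = 0.54 - 0.46 * cos(2 * pi * k / order),
    hann = 0.5 - 0.5 * cos(2 * pi * k / order),
    rectangular = rep(1, n)
  )
  h <- h * w
  h <- h / sum(h)  # exact unit DC gain
  filter_spec("fir", h, 1, fs,
              params = list(order = order, cutoff = cutoff, window = window),
              group_delay = order / 2)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Complex frequency response of a filter
#'
#' @param spec A `filter_spec`.
#' @param freq_hz Frequencies at which to evaluate (Hz).
#' @return Complex vector `H(e^{j 2 pi f / fs})`.
#' @export
freq_response <- function(spec, freq_hz) {
  z <- exp(-1i * 2 * pi * freq_hz / spec$fs)
  num <- outer(z, seq_along(spec$b) - 1, `^`) %*% spec$b
  den <- outer(z, seq_along(spec$a) - 1, `^`) %*% spec$a
  as.vector(num / den)
}

#' Frequency-response table
#'
#' @param spec A `filter_spec`.
#' @param freq_hz Frequency grid (Hz); default 0 to Nyquist in 0.5 Hz steps.
#' @return Data frame `freq_hz, gain_db, phase_deg`.
#' @export
freq_response_table <- function(spec, freq_hz = seq(0, spec$fs / 2, by = 0.5)) {
  H <- freq_response(spec, freq_hz)
  data.frame(freq_hz = freq_hz,
             gain_db = 20 * log10(pmax(Mod(H), 1e-300)),
             phase_deg = Arg(H) * 180 / pi)
}

#' Apply a filter to an ECG record
#'
#' The record is reflect-padded before filtering and cropped afterwards, so
#' the output has the input's length and boundary transients do not shift
#' fiducials. For linear-phase FIR filters, `compensate_delay = TRUE`
#' (default) shifts the output by the (rounded) group delay so fiducial
#' timing is preserved.
#'
#' @param record An `ecg_record`.
#' @param spec A `filter_spec` with matching `fs`.
#' @param compensate_delay Compensate the FIR group delay?
#' @return A filtered `ecg_record` of the same length.
#' @export
apply_filter <- function(record, spec, compensate_delay = TRUE) {
  stopifnot(inherits(record, "ecg_record"), inherits(spec, "filter_spec"))
  if (abs(spec$fs - record$fs) > 1e-9 * spec$fs) {
    stop(sprintf("sampling-rate mismatch: record %g Hz, filter %g Hz",
                 record$fs, spec$fs), call. = FALSE)
  }
  x <- record$values
  n <- length(x)
  if (n == 0) stop("empty record", call. = FALSE)
  # reflect padding long enough for both the FIR length and the notch
  # transient (Q = 10 at 50 Hz decays in well under a second)
  p <- min(n - 1L, max(3L * length(spec$b), as.integer(record$fs)))
  xp <- if (p > 0) c(x[(p + 1):2], x, x[(n - 1):(n - p)]) else x
  yp <- as.numeric(signal::filter(spec$b, spec$a, xp))
  gd <- if (compensate_delay) as.integer(round(spec$group_delay)) else 0L
  start <- p + 1L + gd
  y <- yp[start:(start + n - 1L)]
  if (anyNA(y)) {
    # delay compensation ran past the padded end; extend with last value
    y[is.na(y)] <- yp[length(yp)]
  }
  ecg_record(y, record$fs, record$start_time)
}

#' Export filter coefficients as CSV
#'
#' @param spec A `filter_spec`.
#' @param path Output path; columns `index,b,a` (a padded with 0).
#' @export
write_filter_coefficients <- function(spec, path) {
  nb <- length(spec$b); na <- length(spec$a)
  len <- max(nb, na)
  df <- data.frame(index = 0:(len - 1),
                   b = c(spec$b, rep(0, len - nb)),
                   a = c(spec$a, rep(0, len - na)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Optional analog-front-end emulation: 0.5-40 Hz band-pass
#'
#' A Butterworth band-pass standing in for the instrumentation front end
#' of a single-lead acquisition chain. Off by default in the pipeline.
#'
#' @param fs Sampling rate (Hz).
#' @param band Passband edges (Hz).
#' @param order Butterworth order per edge.
#' @return A `filter_spec`.
#' @export
design_frontend_bandpass <- function(fs = 500, band = c(0.5, 40), order = 2) {
  stopifnot(band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  bt <- signal::butter(order, band / (fs / 2), type = "pass")
  filter_spec("frontend-bandpass", bt$b, bt$a, fs,
              params = list(band = band, order = order), group_delay = 0)
}
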