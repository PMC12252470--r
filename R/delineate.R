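#' Delineation configuration
#'
#' Free parameters of the derivative-based delineator. Search windows are
#' in seconds relative to the R peak and must be ordered and
#' non-overlapping (P < Q < R < S < T). `wave_polarity` encodes the
#' expected deflection sign of each wave (+1 upward, -1 downward); the
#' delineator confirms it against the second derivative at each candidate,
#' so swapping the map delineates an inverted lead.
#'
#' @param refractory_s Minimum spacing between R peaks (s).
#' @param r_band Band-pass edges (Hz) for the R-detection pre-filter; the
#'   5-20 Hz band concentrates QRS energy.
#' @param threshold_frac Fraction of the rolling maximum used as the
#'   adaptive detection threshold.
#' @param rolling_s Width of the rolling-maximum window (s).
#' @param windows Named list of `c(lo, hi)` search windows (s, relative to
#'   R) for waves `p`, `q`, `s`, `t`.
#' @param onset_frac Onset/offset rule: boundary placed where the absolute
#'   first derivative falls below this fraction of the flank maximum.
#' @param prominence_frac Minimum wave deviation from the window median,
#'   as a fraction of the R deviation, below which a wave is reported
#'   absent rather than fabricated.
#' @param wave_polarity Named vector of +1/-1 for waves p, q, s, t.
#' @return A `delineation_config` object.
#' @export
delineation_config <- function(refractory_s = 0.2,
                               r_band = c(5, 20),
                               threshold_frac = 0.5,
                               rolling_s = 2,
                               windows = list(p = c(-0.30, -0.08),
                                              q = c(-0.06, -0.005),
                                              s = c(0.005, 0.06),
                                              t = c(0.12, 0.45)),
                               onset_frac = 0.10,
                               prominence_frac = 0.05,
                               wave_polarity = c(p = 1, q = -1, s = -1,
                                                 t = 1)) {
  stopifnot(refractory_s > 0, threshold_frac > 0, threshold_frac < 1,
            onset_frac > 0, onset_frac < 1)
  need <- c("p", "q", "s", "t")
  if (!all(need %in% names(windows))) {
    stop("windows must name waves p, q, s, t", call. = FALSE)
  }
  if (!(windows$p[2] <= windows$q[1] && windows$q[2] < 0 &&
        windows$s[1] > 0 && windows$s[2] <= windows$t[1])) {
    stop("search windows must be non-overlapping and ordered P < Q < R < S < T",
         call. = FALSE)
  }
  structure(list(refractory_s = refractory_s, r_band = r_band,
                 threshold_frac = threshold_frac, rolling_s = rolling_s,
                 windows = windows, onset_frac = onset_frac,
                 prominence_frac = prominence_frac,
                 wave_polarity = wave_polarity),
            class = "delineation_config")
}

#' Numerical differentiation of a record
#'
#' Central differences on interior samples, one-sided at the endpoints,
#' scaled to physical units: mV/s for order 1 (scale fs), mV/s^2 for
#' order 2 (scale fs^2).
#'
#' @param record An `ecg_record`.
#' @param order 1 or 2.
#' @return Numeric vector, same length as the record.
#' @export
differentiate <- function(record, order = 1) {
  stopifnot(inherits(record, "ecg_record"), order %in% c(1, 2))
  x <- record$values
  n <- length(x)
  if (n < 3) stop("record too short to differentiate (need >= 3 samples)",
                  call. = FALSE)
  fs <- record$fs
  if (order == 1) {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2 * fs
    d[1] <- (x[2] - x[1]) * fs
    d[n] <- (x[n] - x[n - 1]) * fs
  } else {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * fs^2
    d[1] <- d[2]
    d[n] <- d[n - 1]
  }
  d
}

rolling_max <- function(x, k) {
  k <- min(k, length(x))
  if (k %% 2 == 0) k <- k + 1
  if (k >= length(x)) return(rep(max(x), length(x)))
  r <- zoo::rollmax(x, k, fill = NA, align = "center")
  h <- (k - 1) / 2
  r[seq_len(h)] <- r[h + 1]
  r[(length(x) - h + 1):length(x)] <- r[length(x) - h]
  r
}

#' Detect R peaks
#'
#' Candidate cycles are found by adaptive thresholding of a 5-20 Hz
#' band-passed copy of the signal (threshold = `threshold_frac` times a
#' rolling maximum of the envelope); each candidate is refined to the
#' local maximum of the raw signal within +/- 50 ms, and peaks closer than
#' the refractory period are resolved in favour of the larger raw
#' amplitude. Amplitude-scale invariant by construction.
#'
#' @param record An `ecg_record` of duration >= 2 s.
#' @param config A [delineation_config()].
#' @return Integer vector of R sample indices (1-based), possibly empty.
#' @export
detect_r_peaks <- function(record, config = delineation_config()) {
  stopifnot(inherits(record, "ecg_record"))
  if (anyNA(record$values)) stop("record contains NA values", call. = FALSE)
  if (duration(record) < 2) {
    stop("record must be at least 2 s long for R detection", call. = FALSE)
  }
  fs <- record$fs
  bp <- design_frontend_bandpass(fs, band = config$r_band, order = 2)
  env <- abs(as.numeric(signal::filtfilt(bp$b, bp$a, record$values)))
  if (max(env) <= 0) return(integer(0))
  thr <- config$threshold_frac * rolling_max(env, as.integer(config$rolling_s * fs))
  floor_amp <- 0.05 * max(env)  # ignore near-silent stretches (scale-invariant)
  active <- env >= pmax(thr, floor_amp)
  if (!any(active)) return(integer(0))
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- integer(0)
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    cand <- c(cand, seg[which.max(env[seg])])
  }
  # refine to raw-signal maximum within +/- 50 ms
  half <- as.integer(round(0.05 * fs))
  x <- record$values
  n <- length(x)
  refined <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # refractory: keep the larger raw amplitude of any conflicting pair
  refr <- config$refractory_s * fs
  keep <- integer(0)
  for (i in refined) {
    if (length(keep) && (i - keep[length(keep)]) < refr) {
      if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  keep
}

# first-derivative zero crossings inside idx range; returns candidate
# extremum indices
zero_crossings <- function(d1, idx) {
  if (length(idx) < 2) return(integer(0))
  a <- d1[idx[-length(idx)]]
  b <- d1[idx[-1]]
  cr <- which(a * b < 0 | (a != 0 & b == 0))
  out <- integer(length(cr))
  for (j in seq_along(cr)) {
    i <- idx[cr[j]]
    out[j] <- if (abs(d1[i + 1]) < abs(d1[i])) i + 1L else i
  }
  unique(out)
}

# walk from a wave peak outward until |d1| drops below onset_frac of the
# flank maximum seen so far
wave_boundary <- function(d1, peak, direction, limit, onset_frac) {
  i <- peak
  flank_max <- 0
  while ((direction < 0 && i > limit) || (direction > 0 && i < limit)) {
    i <- i + direction
    a <- abs(d1[i])
    if (a > flank_max) flank_max <- a
    if (flank_max > 0 && a < onset_frac * flank_max) return(i)
  }
  limit
}

locate_wave <- function(x, d1, d2, win_idx, polarity, r_amp, med,
                        prominence_frac) {
  cand <- zero_crossings(d1, win_idx)
  if (!length(cand)) return(NA_integer_)
  ok <- if (polarity > 0) d2[cand] < 0 else d2[cand] > 0
  cand <- cand[ok]
  if (!length(cand)) return(NA_integer_)
  dev <- polarity * (x[cand] - med)
  best <- cand[which.max(dev)]
  if (dev[which.max(dev)] < prominence_frac * abs(r_amp - med)) {
    return(NA_integer_)
  }
  best
}

#' Locate P, Q, R, S, T fiducials
#'
#' Within each configured search window around every detected R peak, wave
#' peaks are candidate zero crossings of the first derivative whose
#' polarity is confirmed by the second derivative (negative curvature for
#' an upward P/T, positive for a downward Q/S). Onsets/offsets are placed
#' where the absolute first derivative falls below `onset_frac` of the
#' flank maximum. The returned `q` and `s` columns are the QRS onset and
#' offset (boundaries of the Q and S waves); absent P/T waves give NA,
#' never a fabricated index; a beat whose Q or S wave cannot be located is
#' dropped.
#'
#' @param record An `ecg_record`.
#' @param r_peaks Sorted integer R indices from [detect_r_peaks()].
#' @param config A [delineation_config()].
#' @return A `fiducial_set`: data frame with columns `beat, p_on, p_peak,
#'   q, r, s, t_peak, t_off` (1-based sample indices) and attribute `fs`.
#' @export
locate_fiducials <- function(record, r_peaks, config = delineation_config()) {
  stopifnot(inherits(record, "ecg_record"))
  if (!length(r_peaks)) stop("r_peaks must be non-empty", call. = FALSE)
  if (is.unsorted(r_peaks, strictly = TRUE)) {
    stop("r_peaks must be strictly increasing", call. = FALSE)
  }
  x <- record$values
  fs <- record$fs
  n <- length(x)
  d1 <- differentiate(record, 1)
  d2 <- differentiate(record, 2)
  pol <- config$wave_polarity
  w <- config$windows
  rows <- vector("list", length(r_peaks))
  for (b in seq_along(r_peaks)) {
    r <- r_peaks[b]
    lo_lim <- if (b > 1) floor((r + r_peaks[b - 1]) / 2) else 1L
    hi_lim <- if (b < length(r_peaks)) floor((r + r_peaks[b + 1]) / 2) else n
    win <- function(wv) {
      lo <- max(lo_lim, r + as.integer(round(wv[1] * fs)))
      hi <- min(hi_lim, r + as.integer(round(wv[2] * fs)))
      if (lo >= hi) return(integer(0))
      lo:hi
    }
    med <- stats::median(x[max(lo_lim, r - as.integer(0.4 * fs)):
                           min(hi_lim, r + as.integer(0.5 * fs))])
    p_pk <- locate_wave(x, d1, d2, win(w$p), pol[["p"]], x[r], med,
                        config$prominence_frac)
    q_pk <- locate_wave(x, d1, d2, win(w$q), pol[["q"]], x[r], med,
                        config$prominence_frac)
    s_pk <- locate_wave(x, d1, d2, win(w$s), pol[["s"]], x[r], med,
                        config$prominence_frac)
    t_pk <- locate_wave(x, d1, d2, win(w$t), pol[["t"]], x[r], med,
                        config$prominence_frac)
    if (is.na(q_pk) || is.na(s_pk)) next  # beat dropped
    q_on <- wave_boundary(d1, q_pk, -1L, lo_lim, config$onset_frac)
    s_off <- wave_boundary(d1, s_pk, +1L, hi_lim, config$onset_frac)
    p_on <- if (is.na(p_pk)) NA_integer_ else
      wave_boundary(d1, p_pk, -1L, lo_lim, config$onset_frac)
    t_off <- if (is.na(t_pk)) NA_integer_ else
      wave_boundary(d1, t_pk, +1L, hi_lim, config$onset_frac)
    rows[[b]] <- data.frame(beat = b, p_on = p_on, p_peak = p_pk,
                            q = q_on, r = r, s = s_off,
                            t_peak = t_pk, t_off = t_off)
  }
  fid <- do.call(rbind, rows)
  if (is.null(fid)) {
    fid <- data.frame(beat = integer(0), p_on = integer(0),
                      p_peak = integer(0), q = integer(0), r = integer(0),
                      s = integer(0), t_peak = integer(0), t_off = integer(0))
  }
  fid$beat <- seq_len(nrow(fid))
  structure(fid, fs = fs, class = c("fiducial_set", "data.frame"))
}

#' Per-beat ECG intervals
#'
#' RR between consecutive R peaks (assigned to the earlier beat, NA for the
#' last); PR from P onset to QRS onset; QRS from QRS onset to QRS offset;
#' QT from QRS onset to T offset; ST from QRS offset to the T-onset proxy
#' (the T peak mirrored about its offset, i.e. `2 t_peak - t_off`). Beats
#' with absent required landmarks yield NA for the affected intervals.
#'
#' @param fiducials A `fiducial_set` (or the `ground_truth` fiducial data
#'   frame with an `fs` attribute supplied via `fs`).
#' @param fs Sampling rate; defaults to the `fs` attribute of `fiducials`.
#' @return Data frame `beat, rr_s, pr_s, st_s, qrs_s, qt_s`.
#' @export
compute_intervals <- function(fiducials, fs = attr(fiducials, "fs")) {
  if (is.null(fs)) stop("sampling rate unknown; pass `fs`", call. = FALSE)
  f <- as.data.frame(fiducials)
  nb <- nrow(f)
  rr <- c(diff(f$r), NA) / fs
  pr <- (f$q - f$p_on) / fs
  qrs <- (f$s - f$q) / fs
  qt <- (f$t_off - f$q) / fs
  t_on_proxy <- 2 * f$t_peak - f$t_off
  st <- (t_on_proxy - f$s) / fs
  data.frame(beat = f$beat, rr_s = rr, pr_s = pr, st_s = st,
             qrs_s = qrs, qt_s = qt)
}

#' Write fiducials / intervals as CSV
#'
#' Fiducials use 0-based sample indices on disk; absent waves are empty
#' cells.
#' @param fiducials A `fiducial_set`.
#' @param path Output path.
#' @export
write_fiducials <- function(fiducials, path) {
  out <- as.data.frame(fiducials)
  idx_cols <- setdiff(names(out), "beat")
  out[idx_cols] <- lapply(out[idx_cols], function(v) v - 1L)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_fiducials
#' @param intervals Data frame from [compute_intervals()].
#' @export
write_intervals <- function(intervals, path) {
  utils::write.csv(intervals, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
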