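#' Beat morphology template: five Gaussian waves
#'
#' Each beat is modelled as the sum of five Gaussian bumps (P, Q, R, S, T),
#' each described by an amplitude (mV), a center offset relative to the R
#' peak (s) and a width sigma (s). This keeps every landmark analytic:
#' wave peaks sit at the bump centers and onsets/offsets at +/- 2.5 sigma.
#'
#' @param p,q,r,s,t Length-3 numeric vectors `c(amplitude_mv, center_s,
#'   width_s)`.
#' @param baseline_mv Constant baseline offset (mV).
#' @return A `beat_template` object.
#' @examples
#' tpl <- beat_template()  # resting adult morphology defaults
#' @export
beat_template <- function(p = c(0.15, -0.22, 0.025),
                          q = c(-0.10, -0.04, 0.010),
                          r = c(1.00, 0.00, 0.012),
                          s = c(-0.15, 0.04, 0.010),
                          t = c(0.30, 0.30, 0.045),
                          baseline_mv = 0) {
  waves <- list(p = p, q = q, r = r, s = s, t = t)
  for (nm in names(waves)) {
    w <- waves[[nm]]
    if (length(w) != 3 || !is.numeric(w)) {
      stop("wave `", nm, "` must be c(amplitude, center, width)", call. = FALSE)
    }
    if (w[3] <= 0) stop("wave `", nm, "` width must be > 0", call. = FALSE)
  }
  amps <- vapply(waves, `[`, numeric(1), 1)
  centers <- vapply(waves, `[`, numeric(1), 2)
  if (amps[["r"]] <= 0) stop("R amplitude must be > 0", call. = FALSE)
  if (any(abs(amps[-3]) >= amps[["r"]])) {
    stop("R amplitude must be strictly largest in magnitude", call. = FALSE)
  }
  if (is.unsorted(centers, strictly = TRUE)) {
    stop("wave centers must be strictly ordered P < Q < R < S < T",
         call. = FALSE)
  }
  structure(list(waves = waves, baseline_mv = baseline_mv),
            class = "beat_template")
}

#' RR-interval series specification
#'
#' RR intervals are a mean level plus low-frequency (sympathetic/baroreflex
#' band) and high-frequency (respiratory band) sinusoidal modulation plus
#' white Gaussian jitter:
#' `RR_i = mean_rr + lf_amp sin(2 pi lf_freq t_i) + hf_amp sin(2 pi hf_freq t_i) + e_i`,
#' evaluated at the running beat time `t_i`.
#'
#' @param n_beats Number of intervals to generate.
#' @param mean_rr Mean RR interval (s).
#' @param lf_amp,lf_freq LF modulation amplitude (s) and frequency (Hz);
#'   default frequency 0.095 Hz, the conventional LF band center.
#' @param hf_amp,hf_freq HF modulation amplitude (s) and frequency (Hz);
#'   default frequency 0.275 Hz, the conventional HF band center.
#' @param jitter_sd White jitter standard deviation (s).
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   series.
#' @return An `rr_series_spec` object.
#' @export
rr_series_spec <- function(n_beats, mean_rr = 0.8,
                           lf_amp = 0, lf_freq = 0.095,
                           hf_amp = 0, hf_freq = 0.275,
                           jitter_sd = 0, seed = 1L) {
  stopifnot(n_beats >= 1, mean_rr > 0, lf_amp >= 0, hf_amp >= 0,
            jitter_sd >= 0, lf_freq > 0, hf_freq > 0)
  if (mean_rr - lf_amp - hf_amp - 5 * jitter_sd <= 0.2) {
    stop("spec can produce RR <= 0.2 s: require mean_rr - lf_amp - hf_amp",
         " - 5*jitter_sd > 0.2", call. = FALSE)
  }
  structure(list(n_beats = as.integer(n_beats), mean_rr = mean_rr,
                 lf_amp = lf_amp, lf_freq = lf_freq,
                 hf_amp = hf_amp, hf_freq = hf_freq,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "rr_series_spec")
}

#' Generate an RR-interval series
#'
#' @param spec An [rr_series_spec()].
#' @return A list with `rr` (intervals, s) and `beat_times` (cumulative time
#'   of each beat, s, starting at 0; length `n_beats + 1` counting the
#'   initial beat at t = 0).
#' @export
generate_rr_series <- function(spec) {
  stopifnot(inherits(spec, "rr_series_spec"))
  set.seed(spec$seed)
  jit <- stats::rnorm(spec$n_beats, 0, spec$jitter_sd)
  rr <- numeric(spec$n_beats)
  t_i <- 0
  times <- numeric(spec$n_beats + 1)
  for (i in seq_len(spec$n_beats)) {
    rr[i] <- spec$mean_rr +
      spec$lf_amp * sin(2 * pi * spec$lf_freq * t_i) +
      spec$hf_amp * sin(2 * pi * spec$hf_freq * t_i) +
      jit[i]
    t_i <- t_i + rr[i]
    times[i + 1] <- t_i
  }
  if (any(rr <= 0.2)) {
    stop("generated RR interval <= 0.2 s; tighten the spec", call. = FALSE)
  }
  list(rr = rr, beat_times = times)
}

#' Additive noise specification
#'
#' Emulates the dominant contaminants of wearable single-lead ECG:
#' powerline interference (50 Hz by default), baseline wander
#' (a slow sinusoid, default 0.25 Hz) and broadband white noise.
#' An all-zero spec leaves the clean signal untouched, exactly.
#'
#' @param powerline_amp,powerline_freq Powerline sinusoid amplitude (mV)
#'   and frequency (Hz).
#' @param baseline_amp,baseline_freq Baseline-wander amplitude (mV) and
#'   frequency (Hz).
#' @param broadband_sd White-noise standard deviation (mV).
#' @param seed Integer seed for the broadband component.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(powerline_amp = 0, powerline_freq = 50,
                       baseline_amp = 0, baseline_freq = 0.25,
                       broadband_sd = 0, seed = 1L) {
  stopifnot(powerline_amp >= 0, baseline_amp >= 0, broadband_sd >= 0,
            powerline_freq > 0, baseline_freq > 0)
  structure(list(powerline_amp = powerline_amp, powerline_freq = powerline_freq,
                 baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 broadband_sd = broadband_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

wave_value <- function(tt, amp, center, width) {
  amp * exp(-((tt - center)^2) / (2 * width^2))
}

#' Generate a synthetic single-lead ECG with ground truth
#'
#' Places one template beat at every beat time of the RR series, sums the
#' five Gaussian waves, adds noise last, and returns the per-beat true
#' fiducials. Ground-truth columns: `p_on` (P center - 2.5 sigma_P),
#' `p_peak`, `q` (QRS onset, Q center - 2.5 sigma_Q), `r`, `s` (QRS offset,
#' S center + 2.5 sigma_S), `t_peak`, `t_off` (T center + 2.5 sigma_T), all
#' 0-based sample indices.
#'
#' @param template A [beat_template()].
#' @param rr_spec An [rr_series_spec()]; `n_beats` intervals place
#'   `n_beats + 1` beats, so the true RR series has length `n_beats`.
#' @param noise A [noise_spec()].
#' @param fs Sampling rate in Hz; must be >= 200 for the QRS to be resolved.
#' @param pad Quiet time (s) prepended and appended so the first P and last
#'   T fit inside the record.
#' @return A list with `record` (`ecg_record`), `truth` (a `ground_truth`
#'   list: `fiducials` data frame, `rr`, `beat_times`).
#' @export
generate_ecg <- function(template = beat_template(),
                         rr_spec = rr_series_spec(10),
                         noise = noise_spec(),
                         fs = 500, pad = 0.5) {
  stopifnot(inherits(template, "beat_template"),
            inherits(rr_spec, "rr_series_spec"),
            inherits(noise, "noise_spec"))
  if (fs < 200) {
    stop("fs must be >= 200 Hz to resolve QRS morphology (got ", fs, " Hz)",
         call. = FALSE)
  }
  series <- generate_rr_series(rr_spec)
  beat_times <- pad + series$beat_times
  dur <- beat_times[length(beat_times)] + pad
  n <- floor(dur * fs) + 1
  tt <- (seq_len(n) - 1) / fs

  x <- rep(template$baseline_mv, n)
  for (bt in beat_times) {
    for (w in template$waves) {
      # evaluate only within +/- 6 sigma of the bump: exact to ~1e-8
      lo <- max(1L, floor((bt + w[2] - 6 * w[3]) * fs) + 1L)
      hi <- min(n, ceiling((bt + w[2] + 6 * w[3]) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + wave_value(tt[idx], w[1], bt + w[2], w[3])
    }
  }
  clean <- x
  if (noise$powerline_amp > 0) {
    x <- x + noise$powerline_amp * sin(2 * pi * noise$powerline_freq * tt)
  }
  if (noise$baseline_amp > 0) {
    x <- x + noise$baseline_amp * sin(2 * pi * noise$baseline_freq * tt)
  }
  if (noise$broadband_sd > 0) {
    set.seed(noise$seed)
    x <- x + stats::rnorm(n, 0, noise$broadband_sd)
  }

  wv <- template$waves
  idx_of <- function(offset) as.integer(round((beat_times + offset) * fs)) + 1L
  fid <- data.frame(
    beat = seq_along(beat_times),
    p_on   = idx_of(wv$p[2] - 2.5 * wv$p[3]),
    p_peak = idx_of(wv$p[2]),
    q      = idx_of(wv$q[2] - 2.5 * wv$q[3]),
    r      = idx_of(0),
    s      = idx_of(wv$s[2] + 2.5 * wv$s[3]),
    t_peak = idx_of(wv$t[2]),
    t_off  = idx_of(wv$t[2] + 2.5 * wv$t[3])
  )
  truth <- structure(
    list(fiducials = fid, rr = series$rr, beat_times = beat_times, fs = fs),
    class = "ground_truth"
  )
  list(record = ecg_record(x, fs), clean = ecg_record(clean, fs),
       truth = truth)
}

#' Write ground-truth fiducials as CSV
#'
#' Header `beat,p_on,p_peak,q,r,s,t_peak,t_off`, 0-based sample indices.
#' @param truth A `ground_truth` object from [generate_ecg()].
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  fid <- truth$fiducials
  out <- fid
  idx_cols <- setdiff(names(out), "beat")
  out[idx_cols] <- lapply(out[idx_cols], function(v) v - 1L)  # 0-based on disk
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default per-class feature distributions for exercise intensity
#'
#' Five intensity levels (rest plus four cycling checkpoints). Means follow
#' exercise physiology: RR, PR, ST and QT shorten and HRV (SDNN, LF, HF)
#' collapses as intensity rises; QRS duration is nearly constant.
#' Rows are classes 0..K-1, columns the 8 features in the canonical order
#' `rr, pr, st, qrs, qt` (s), `sdnn` (ms), `lf, hf` (ms^2).
#'
#' @return A list with `means` (5 x 8 matrix) and `sds` (length-8 vector).
#' @export
default_intensity_features <- function() {
  feat <- c("rr", "pr", "st", "qrs", "qt", "sdnn", "lf", "hf")
  means <- rbind(
    c(0.85, 0.160, 0.120, 0.095, 0.380, 60, 900, 800),
    c(0.77, 0.150, 0.105, 0.092, 0.355, 50, 750, 650),
    c(0.69, 0.140, 0.090, 0.089, 0.330, 40, 600, 500),
    c(0.61, 0.130, 0.075, 0.086, 0.305, 30, 450, 350),
    c(0.53, 0.120, 0.060, 0.083, 0.280, 20, 300, 200)
  )
  colnames(means) <- feat
  sds <- c(rr = 0.025, pr = 0.012, st = 0.015, qrs = 0.008, qt = 0.025,
           sdnn = 5, lf = 60, hf = 60)
  list(means = means, sds = sds)
}

#' Exercise-intensity dataset specification
#'
#' Class-conditional Gaussian feature vectors: class k draws each of the 8
#' features independently from `N(means[k, j], sds[j])`. The per-class RR
#' mean must strictly decrease with class index (heart rate rises with
#' intensity).
#'
#' @param n_classes Number of intensity levels K (>= 2).
#' @param n_per_class Samples per class (>= 10).
#' @param means K x 8 matrix of per-class feature means (columns in the
#'   canonical order rr, pr, st, qrs, qt, sdnn, lf, hf).
#' @param sds Length-8 vector (or K x 8 matrix) of standard deviations,
#'   all > 0.
#' @param split Train/validation/test fractions, summing to 1.
#' @param seed Root seed.
#' @return An `intensity_class_spec` object.
#' @export
intensity_class_spec <- function(n_classes = 5, n_per_class = 200,
                                 means = NULL, sds = NULL,
                                 split = c(train = 0.6, validation = 0.2,
                                           test = 0.2),
                                 seed = 42L) {
  def <- default_intensity_features()
  if (is.null(means)) means <- def$means[seq_len(n_classes), , drop = FALSE]
  if (is.null(sds)) sds <- def$sds
  if (n_classes < 2) stop("need at least 2 classes", call. = FALSE)
  if (n_per_class < 10) stop("need n_per_class >= 10", call. = FALSE)
  if (nrow(means) != n_classes || ncol(means) != 8) {
    stop("`means` must be a ", n_classes, " x 8 matrix", call. = FALSE)
  }
  if (is.matrix(sds)) {
    if (any(dim(sds) != c(n_classes, 8))) stop("`sds` matrix must be K x 8",
                                               call. = FALSE)
  } else if (length(sds) != 8) {
    stop("`sds` must have 8 entries", call. = FALSE)
  }
  if (any(sds <= 0)) stop("all feature sds must be > 0", call. = FALSE)
  if (is.unsorted(rev(means[, 1]), strictly = TRUE)) {
    stop("per-class mean RR must strictly decrease with class index",
         call. = FALSE)
  }
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1",
                                       call. = FALSE)
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 means = means, sds = sds, split = split,
                 seed = as.integer(seed)),
            class = "intensity_class_spec")
}

#' Generate a labelled exercise-intensity dataset
#'
#' @param spec An [intensity_class_spec()].
#' @return A `labeled_dataset` list: `x` (n x 8 feature matrix), `y`
#'   (integer labels 0..K-1), `split` (factor with levels
#'   train/validation/test, stratified by class), `spec`.
#' @export
generate_intensity_dataset <- function(spec = intensity_class_spec()) {
  stopifnot(inherits(spec, "intensity_class_spec"))
  set.seed(spec$seed)
  K <- spec$n_classes
  npc <- spec$n_per_class
  sds <- spec$sds
  xs <- vector("list", K)
  for (k in seq_len(K)) {
    sk <- if (is.matrix(sds)) sds[k, ] else sds
    xs[[k]] <- matrix(stats::rnorm(npc * 8, mean = rep(spec$means[k, ],
                                                       each = npc),
                                   sd = rep(sk, each = npc)),
                      nrow = npc)
  }
  x <- do.call(rbind, xs)
  colnames(x) <- colnames(spec$means)
  y <- rep(0:(K - 1), each = npc)
  split <- factor(rep(NA_character_, K * npc),
                  levels = c("train", "validation", "test"))
  for (k in seq_len(K)) {
    rows <- which(y == k - 1)
    rows <- sample(rows)  # stratified, seeded by the root seed
    n_tr <- round(spec$split[[1]] * npc)
    n_va <- round(spec$split[[2]] * npc)
    split[rows[seq_len(n_tr)]] <- "train"
    split[rows[n_tr + seq_len(n_va)]] <- "validation"
    split[rows[(n_tr + n_va + 1):npc]] <- "test"
  }
  structure(list(x = x, y = y, split = split, spec = spec),
            class = "labeled_dataset")
}

#' Write a feature dataset as CSV
#'
#' Header `rr,pr,st,qrs,qt,sdnn,lf,hf,label` plus a `split` column.
#' @param dataset A `labeled_dataset`.
#' @param path Output path.
#' @export
write_dataset <- function(dataset, path) {
  df <- as.data.frame(dataset$x)
  df$label <- dataset$y
  df$split <- as.character(dataset$split)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
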