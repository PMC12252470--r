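test_that("sdnn: exact small cases and the Gaussian oracle", {
  expect_equal(sdnn(rep(0.8, 10)), 0)
  expect_equal(sdnn(rep(c(0.8, 1.0), 10)), 100)  # population SD, exact
  set.seed(31)
  rr <- stats::rnorm(1000, 0.9, 0.05)
  expect_lt(abs(sdnn(rr) - 50) / 50, 0.1)
  expect_error(sdnn(0.8), "2 RR")
})

test_that("constant RR gives zero LF and HF power", {
  bt <- seq(0.8, 300, by = 0.8)
  sp <- hrv_spectrum(bt, rep(0.8, length(bt)))
  expect_equal(sp$lf_power, 0, tolerance = 1e-10)
  expect_equal(sp$hf_power, 0, tolerance = 1e-10)
  expect_true(is.na(sp$lf_hf_ratio))
})

test_that("0.10 Hz RR modulation lands in LF with Parseval-level power", {
  bt <- seq(0.8, 300, by = 0.8)
  rr <- 0.8 + 0.030 * sin(2 * pi * 0.10 * bt)
  sp <- hrv_spectrum(bt, rr)
  expect_gt(sp$lf_hf_ratio, 10)
  parseval <- (0.030 * 1000)^2 / 2  # ms^2
  expect_lt(abs(sp$lf_power + sp$hf_power - parseval) / parseval, 0.25)
})

test_that("0.25 Hz RR modulation lands in HF", {
  bt <- seq(0.8, 300, by = 0.8)
  rr <- 0.8 + 0.030 * sin(2 * pi * 0.25 * bt)
  sp <- hrv_spectrum(bt, rr)
  expect_gt(sp$hf_power, sp$lf_power)
})

test_that("HRV powers are invariant to a constant shift of beat times", {
  bt <- seq(0.8, 300, by = 0.8)
  rr <- 0.8 + 0.02 * sin(2 * pi * 0.1 * bt) + 0.01 * sin(2 * pi * 0.25 * bt)
  a <- hrv_spectrum(bt, rr)
  b <- hrv_spectrum(bt + 1234.5, rr)
  expect_equal(a$lf_power, b$lf_power)
  expect_equal(a$hf_power, b$hf_power)
  expect_equal(sdnn(rr), sdnn(rr))
})

test_that("total HRV spectral power tracks the series variance", {
  set.seed(13)
  bt <- seq(0.8, 300, by = 0.8)
  rr <- 0.8 + 0.02 * sin(2 * pi * 0.1 * bt) + 0.015 * sin(2 * pi * 0.3 * bt)
  sp <- hrv_spectrum(bt, rr)
  grid <- seq(min(bt), max(bt), by = 0.25)
  vref <- stats::var(stats::spline(bt, rr * 1000, xout = grid)$y)
  expect_lt(abs(sp$total_power - vref) / vref, 0.25)
})

test_that("hrv_spectrum enforces its minimum record length", {
  expect_error(hrv_spectrum(seq(1, 20), rep(0.8, 20)), "60 s")
})

test_that("signal band power: zero signal and a 10 Hz tone", {
  expect_equal(signal_band_power(ecg_record(numeric(4000), 500), 5, 20), 0)
  tone <- ecg_record(sin(2 * pi * 10 * seq(0, 20, by = 1 / 500)), 500)
  inband <- signal_band_power(tone, 5, 20)
  total <- signal_band_power(tone, 0.1, 249.9)
  expect_gt(inband / total, 0.95)
  expect_error(signal_band_power(tone, 20, 5), "exceed")
})

test_that("5-20 Hz band power rises with heart rate at fixed morphology", {
  rest <- generate_ecg(rr_spec = rr_series_spec(12, 60 / 65, seed = 1L))
  fast <- generate_ecg(rr_spec = rr_series_spec(28, 60 / 150, seed = 1L))
  expect_gt(signal_band_power(fast$record, 5, 20),
            signal_band_power(rest$record, 5, 20))
})

test_that("agreement metrics: identity, negation, and noise closed form", {
  sim <- clean_sim(n_beats = 29, mean_rr = 0.9, seed = 3L)
  fid <- locate_fiducials(sim$record, detect_r_peaks(sim$record))
  self <- agreement_metrics(sim$record, sim$record, fid, fid)
  expect_equal(self$pearson_r, 1.0)
  expect_equal(self$mean_rr_diff, 0)
  expect_equal(self$mean_pp_diff, 0)
  neg <- ecg_record(-sim$record$values, 500)
  expect_equal(agreement_metrics(sim$record, neg, fid, fid)$pearson_r, -1.0)
  # additive independent noise at SNR s: rho = 1/sqrt(1 + 10^(-s/10))
  set.seed(17)
  x <- sim$record$values
  for (snr_db in c(10, 20)) {
    y <- x + stats::rnorm(length(x), 0, stats::sd(x) / 10^(snr_db / 20))
    r <- agreement_metrics(sim$record, ecg_record(y, 500), fid, fid)$pearson_r
    expect_lt(abs(r - 1 / sqrt(1 + 10^(-snr_db / 10))), 0.02)
  }
  expect_error(agreement_metrics(sim$record,
                                 ecg_record(x[-1], 500), fid, fid),
               "equal length")
})

test_that("agreement is symmetric in its two records", {
  sim <- clean_sim(n_beats = 9, mean_rr = 0.9, seed = 3L)
  set.seed(2)
  other <- ecg_record(sim$record$values + stats::rnorm(length(sim$record$values),
                                                       0, 0.05), 500)
  fa <- locate_fiducials(sim$record, detect_r_peaks(sim$record))
  fb <- locate_fiducials(other, detect_r_peaks(other))
  ab <- agreement_metrics(sim$record, other, fa, fb)
  ba <- agreement_metrics(other, sim$record, fb, fa)
  expect_equal(ab$pearson_r, ba$pearson_r)
  expect_equal(ab$mean_rr_diff, ba$mean_rr_diff)
})

test_that("SNR estimator: cap, constructed 33 dB point, 6 dB doubling", {
  sim <- generate_ecg(rr_spec = rr_series_spec(30, 0.9, seed = 3L), fs = 500)
  fid <- locate_fiducials(sim$clean, detect_r_peaks(sim$clean))
  expect_equal(estimate_snr(sim$clean, fid), 80)  # noiseless -> cap
  x <- sim$clean$values
  f <- as.data.frame(fid)
  qrs_idx <- unlist(mapply(function(a, b) a:b, f$q, f$s, SIMPLIFY = FALSE))
  s_rms <- sqrt(mean(x[qrs_idx]^2))
  sd33 <- s_rms / 10^(33 / 20)
  set.seed(5)
  noise <- stats::rnorm(length(x), 0, sd33)
  est33 <- estimate_snr(ecg_record(x + noise, 500), fid)
  expect_lt(abs(est33 - 33), 2)
  est27 <- estimate_snr(ecg_record(x + 2 * noise, 500), fid)
  expect_lt(abs((est33 - est27) - 6), 1)
})

test_that("feature vector has the canonical order and analytic medians", {
  sim <- clean_sim(n_beats = 100, mean_rr = 0.8, seed = 9L,
                   lf_amp = 0.02, hf_amp = 0.01, jitter_sd = 0.005)
  fid <- locate_fiducials(sim$record, detect_r_peaks(sim$record))
  iv <- compute_intervals(fid)
  hrv <- hrv_metrics(fid$r[-1] / 500, diff(fid$r) / 500)
  fv <- build_feature_vector(iv, hrv)
  expect_named(fv, c("rr", "pr", "st", "qrs", "qt", "sdnn", "lf", "hf"))
  expect_true(all(is.finite(fv)))
  # template-derived analytic interval values, +/- 10 ms
  expect_lt(abs(fv[["rr"]] - 0.8), 0.010)
  expect_lt(abs(fv[["qrs"]] - 0.13), 0.010)
  iv_truth <- compute_intervals(sim$truth$fiducials, fs = 500)
  fv_truth <- build_feature_vector(iv_truth, hrv)
  expect_lt(abs(fv_truth[["pr"]] - 0.2175), 0.010)
  expect_lt(abs(fv_truth[["qt"]] - 0.4775), 0.010)
  expect_error(build_feature_vector(iv[1:3, ], hrv), "5 beats")
})

test_that("identical beats give medians equal to the per-beat values", {
  sim <- clean_sim(n_beats = 9, mean_rr = 0.8, seed = 1L)
  iv <- compute_intervals(sim$truth$fiducials, fs = 500)
  hrv <- list(sdnn = 0, lf_power = 0, hf_power = 0)
  fv <- build_feature_vector(iv, hrv)
  # identical beats up to one sample of index discretization
  expect_equal(fv[["qrs"]], iv$qrs_s[1], tolerance = 1 / 500 / 0.128)
  expect_equal(fv[["pr"]], iv$pr_s[1], tolerance = 1 / 500 / 0.21)
})
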