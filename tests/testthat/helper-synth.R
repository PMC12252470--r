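# Shared fixtures, built in code at test time.

clean_sim <- function(n_beats = 9, mean_rr = 1.0, fs = 500, seed = 1L, ...) {
  generate_ecg(rr_spec = rr_series_spec(n_beats, mean_rr, seed = seed, ...),
               fs = fs)
}

# a small randomized template within resting adult morphology
random_template <- function() {
  beat_template(
    p = c(stats::runif(1, 0.10, 0.20), stats::runif(1, -0.26, -0.18),
          stats::runif(1, 0.020, 0.030)),
    q = c(-stats::runif(1, 0.06, 0.14), stats::runif(1, -0.05, -0.035),
          stats::runif(1, 0.008, 0.012)),
    r = c(stats::runif(1, 0.8, 1.4), 0, stats::runif(1, 0.010, 0.014)),
    s = c(-stats::runif(1, 0.10, 0.20), stats::runif(1, 0.035, 0.05),
          stats::runif(1, 0.008, 0.012)),
    t = c(stats::runif(1, 0.2, 0.4), stats::runif(1, 0.26, 0.33),
          stats::runif(1, 0.035, 0.050))
  )
}
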