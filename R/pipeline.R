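#' Pipeline configuration
#'
#' A nested named list validated against the documented key set; unknown
#' keys are rejected by name so configuration typos cannot silently
#' disable a stage. All randomness derives from `seed` by fixed
#' per-module offsets (generator +0, noise +1, model init +2, training
#' +3), so a run is reproducible from the single root seed. Round-trips
#' losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param fs Sampling rate (Hz).
#' @param input Path of an input record CSV, or NULL to simulate.
#' @param notch_f0,notch_q Notch design parameters.
#' @param fir_order,fir_cutoff FIR design parameters.
#' @param frontend_bandpass Apply the optional 0.5-40 Hz pre-stage?
#' @param delineation A [delineation_config()] (stored as plain list).
#' @param hrv_bands List with `lf` and `hf` band edges (Hz).
#' @param classify Run the classification stage?
#' @param model,training [model_config()] / [training_config()] values
#'   used when `classify = TRUE`.
#' @param n_beats,mean_rr,lf_amp,hf_amp,jitter_sd Simulation parameters
#'   used when `input` is NULL.
#' @param seed Root seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fs = 500, input = NULL,
                            notch_f0 = 50, notch_q = 10,
                            fir_order = 15, fir_cutoff = 50,
                            frontend_bandpass = FALSE,
                            delineation = list(),
                            hrv_bands = list(lf = c(0.04, 0.15),
                                             hf = c(0.15, 0.40)),
                            classify = FALSE,
                            model = list(), training = list(),
                            n_beats = 120, mean_rr = 0.8,
                            lf_amp = 0.02, hf_amp = 0.015,
                            jitter_sd = 0.01, seed = 42L) {
  cfg <- list(fs = fs, input = input, notch_f0 = notch_f0, notch_q = notch_q,
              fir_order = fir_order, fir_cutoff = fir_cutoff,
              frontend_bandpass = frontend_bandpass,
              delineation = delineation, hrv_bands = hrv_bands,
              classify = classify, model = model, training = training,
              n_beats = n_beats, mean_rr = mean_rr, lf_amp = lf_amp,
              hf_amp = hf_amp, jitter_sd = jitter_sd, seed = as.integer(seed))
  validate_pipeline_config(cfg)
}

pipeline_config_keys <- function() {
  c("fs", "input", "notch_f0", "notch_q", "fir_order", "fir_cutoff",
    "frontend_bandpass", "delineation", "hrv_bands", "classify", "model",
    "training", "n_beats", "mean_rr", "lf_amp", "hf_amp", "jitter_sd",
    "seed")
}

validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), pipeline_config_keys())
  if (length(unknown)) {
    stop("unknown pipeline configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(pipeline_config_keys(), names(cfg))
  for (k in missing) cfg[k] <- list(NULL)
  structure(cfg[pipeline_config_keys()], class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' Run the full pipeline
#'
#' Stages in order: input (read or simulate) -> conditioning (notch then
#' FIR low-pass, optional front-end band-pass first) -> delineation ->
#' features -> optional classification. Every artifact is written under
#' `out_dir` along with a `manifest.json` listing the configuration hash,
#' seeds and produced files; a stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory artifacts (`record`,
#'   `filtered`, `fiducials`, `intervals`, `features`, and `report` when
#'   classification ran).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  files <- character(0)
  add_file <- function(p) files[[length(files) + 1]] <<- basename(p)

  truth <- NULL
  record <- run_stage("input", {
    if (!is.null(config$input)) {
      read_record(config$input)
    } else {
      sim <- generate_ecg(
        template = beat_template(),
        rr_spec = rr_series_spec(config$n_beats, config$mean_rr,
                                 lf_amp = config$lf_amp,
                                 hf_amp = config$hf_amp,
                                 jitter_sd = config$jitter_sd,
                                 seed = config$seed),
        noise = noise_spec(powerline_amp = 0.1, broadband_sd = 0.02,
                           seed = config$seed + 1L),
        fs = config$fs)
      truth <- sim$truth
      p <- file.path(out_dir, "record.csv")
      write_record(sim$record, p); add_file(p)
      sim$record
    }
  })

  filtered <- run_stage("conditioning", {
    rec <- record
    if (isTRUE(config$frontend_bandpass)) {
      rec <- apply_filter(rec, design_frontend_bandpass(config$fs))
    }
    rec <- apply_filter(rec, design_twin_t_notch(config$notch_f0,
                                                 config$notch_q, config$fs))
    rec <- apply_filter(rec, design_fir_lowpass(config$fir_order,
                                                config$fir_cutoff, config$fs))
    p <- file.path(out_dir, "filtered.csv")
    write_record(rec, p); add_file(p)
    rec
  })

  dcfg <- do.call(delineation_config, config$delineation)
  fiducials <- run_stage("delineation", {
    r <- detect_r_peaks(filtered, dcfg)
    fid <- locate_fiducials(filtered, r, dcfg)
    p <- file.path(out_dir, "fiducials.csv")
    write_fiducials(fid, p); add_file(p)
    fid
  })

  feats <- run_stage("features", {
    iv <- compute_intervals(fiducials)
    p <- file.path(out_dir, "intervals.csv")
    write_intervals(iv, p); add_file(p)
    beat_times <- fiducials$r / config$fs
    hrv <- hrv_metrics(beat_times[-1], diff(fiducials$r) / config$fs,
                       band_lf = config$hrv_bands$lf,
                       band_hf = config$hrv_bands$hf)
    fv <- build_feature_vector(iv, hrv)
    p <- file.path(out_dir, "features.csv")
    utils::write.csv(as.data.frame(t(fv)), p, row.names = FALSE,
                     quote = FALSE)
    add_file(p)
    list(intervals = iv, hrv = hrv, vector = fv)
  })

  report <- NULL
  if (isTRUE(config$classify)) {
    report <- run_stage("classification", {
      mcfg <- do.call(model_config,
                      utils::modifyList(list(seed = config$seed + 2L),
                                        config$model))
      tcfg <- do.call(training_config,
                      utils::modifyList(list(seed = config$seed + 3L),
                                        config$training))
      ds <- generate_intensity_dataset(
        intensity_class_spec(n_classes = mcfg$n_classes, seed = config$seed))
      fit <- train_fcnn(init_model(mcfg), ds, tcfg)
      te <- ds$split == "test"
      rep <- evaluate_model(fit$model, ds$x[te, , drop = FALSE], ds$y[te])
      p <- file.path(out_dir, "history.csv")
      write_history(fit$history, p); add_file(p)
      p <- file.path(out_dir, "confusion.csv")
      utils::write.csv(as.data.frame(rep$confusion), p, quote = FALSE)
      add_file(p)
      cls <- classify(fit$model, feats$vector)
      p <- file.path(out_dir, "classification.csv")
      utils::write.csv(data.frame(label = cls$label,
                                  t(cls$probabilities)), p,
                       row.names = FALSE, quote = FALSE)
      add_file(p)
      rep
    })
  }

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    derived_seeds = list(noise = config$seed + 1L,
                         model_init = config$seed + 2L,
                         training = config$seed + 3L),
    files = files,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(record = record, filtered = filtered, truth = truth,
                 fiducials = fiducials, intervals = feats$intervals,
                 hrv = feats$hrv, features = feats$vector, report = report))
}
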