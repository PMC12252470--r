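#' Uniformly sampled single-channel ECG record
#'
#' The container every pipeline stage consumes and produces: a numeric vector
#' of voltages in millivolts sampled at a constant rate.
#'
#' @param values Numeric vector of voltages (mV).
#' @param fs Sampling rate in Hz (scalar, > 0).
#' @param start_time Time of the first sample in seconds.
#' @return An object of class `ecg_record` with elements `values`, `fs`,
#'   `start_time`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1 * seq(0, 2, by = 1 / 250)), fs = 250)
#' duration(rec)
#' @export
ecg_record <- function(values, fs, start_time = 0) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), fs = as.numeric(fs),
         start_time = as.numeric(start_time)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples @ %g Hz (%.2f s)\n",
              length(x$values), x$fs, duration(x)))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$values)

#' Record duration in seconds
#' @param record An `ecg_record`.
#' @return Duration in seconds.
#' @export
duration <- function(record) length(record$values) / record$fs

#' Sample times of a record
#' @param record An `ecg_record`.
#' @return Numeric vector of times (s), one per sample.
#' @export
sample_times <- function(record) {
  record$start_time + (seq_along(record$values) - 1) / record$fs
}

#' Write an ECG record as CSV
#'
#' Columns `time_s,value_mv`, values printed with 6 decimal places,
#' comma-separated, dot decimal, UTF-8.
#'
#' @param record An `ecg_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  df <- data.frame(
    time_s = sprintf("%.6f", sample_times(record)),
    value_mv = sprintf("%.6f", record$values)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ECG record
#'
#' Reads the `time_s,value_mv` CSV dialect or the plain-text WFDB-style
#' record written by [write_record_wfdb()]. Uniform sampling is verified:
#' the time column must be monotone with a constant step (relative
#' tolerance 1e-6); the first offending row is named on failure.
#'
#' @param path File path (for `format = "wfdb"`, the path of the `.hea`
#'   header or its basename).
#' @param format `"csv"` or `"wfdb"`.
#' @return An `ecg_record`.
#' @export
read_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "wfdb") return(read_record_wfdb(path))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop("empty record file: ", path, call. = FALSE)
  if (!all(c("time_s", "value_mv") %in% names(df))) {
    stop("expected columns `time_s,value_mv` in ", path, call. = FALSE)
  }
  tt <- df$time_s
  if (nrow(df) < 2) stop("record must contain at least 2 samples", call. = FALSE)
  dt <- diff(tt)
  step <- stats::median(dt)
  bad <- which(abs(dt - step) > 1e-6 * max(step, 1e-12))
  if (length(bad) > 0) {
    stop(sprintf(
      "non-uniform sampling: time step at row %d is %.6g s (expected %.6g s)",
      bad[1] + 1, dt[bad[1]], step), call. = FALSE)
  }
  ecg_record(df$value_mv, fs = 1 / step, start_time = tt[1])
}

#' Write a WFDB-style plain-text record
#'
#' A two-file text representation modelled on WFDB record layout: a `.hea`
#' header (record name, sampling rate, sample count, gain in ADC units per
#' mV, resolution bits) and a `.txt` file of integer ADC samples. All files
#' are plain text.
#'
#' @param record An `ecg_record`.
#' @param base Path basename (without extension).
#' @param gain ADC units per millivolt; default 1000 (1 LSB = 1 uV).
#' @param bits Nominal ADC resolution recorded in the header.
#' @return The header path, invisibly.
#' @export
write_record_wfdb <- function(record, base, gain = 1000, bits = 16) {
  stopifnot(inherits(record, "ecg_record"), gain > 0)
  adc <- as.integer(round(record$values * gain))
  hea <- paste0(base, ".hea")
  writeLines(c(
    sprintf("%s 1 %g %d", basename(base), record$fs, length(record$values)),
    sprintf("%s.txt %d %d 0 0 ecg", basename(base), as.integer(gain),
            as.integer(bits)),
    sprintf("# start_time %.6f", record$start_time)
  ), hea)
  writeLines(as.character(adc), paste0(base, ".txt"))
  invisible(hea)
}

read_record_wfdb <- function(path) {
  base <- sub("\\.hea$", "", path)
  hea <- paste0(base, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea, call. = FALSE)
  lines <- readLines(hea)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]  # name nsig fs nsamples
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  gain <- as.numeric(sig[2])
  start_time <- 0
  st <- grep("^# start_time", lines, value = TRUE)
  if (length(st)) start_time <- as.numeric(sub("^# start_time\\s+", "", st[1]))
  adc <- as.numeric(readLines(paste0(base, ".txt")))
  if (length(adc) != n) {
    stop(sprintf("sample file has %d samples, header declares %d",
                 length(adc), n), call. = FALSE)
  }
  ecg_record(adc / gain, fs = fs, start_time = start_time)
}
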