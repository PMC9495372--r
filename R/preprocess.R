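#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass of the stated total order (default
#' 4th order, 20-300 Hz) forward and backward (`signal::filtfilt`), so the
#' output is free of phase distortion.  Forward-backward application
#' doubles the effective roll-off relative to a single pass.
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate in Hz.
#' @param low,high Band edges in Hz; `high` must be below Nyquist.
#' @param order Total filter order (even; default 4 gives two poles per
#'   band edge).
#' @return Filtered signal, same length as `x`.
#' @examples
#' x <- sin(2 * pi * 100 * seq(0, 1, by = 1e-3))
#' y <- bandpass_filter(x, 1000)
#' @export
bandpass_filter <- function(x, sampling_rate, low = 20, high = 300, order = 4) {
  nyq <- sampling_rate / 2
  if (low <= 0 || high >= nyq || low >= high) {
    abort("Band edges must satisfy 0 < low < high < Nyquist.",
          class = "emg_parameter_error")
  }
  if (order < 2 || order %% 2 != 0) {
    abort("`order` must be an even integer >= 2.", class = "emg_parameter_error")
  }
  if (length(x) <= 3 * order) {
    abort("Signal too short for the requested filter order.",
          class = "emg_parameter_error")
  }
  # butter(n, ., "pass") has transfer-function degree 2n, so n = order / 2
  bf <- signal::butter(order / 2, c(low, high) / nyq, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Sliding root-mean-square amplitude
#'
#' RMS over a centered sliding window, one value per fully admissible
#' window position (no padding: the output is shorter than the input by
#' `window - 1` samples).  Value `k` covers samples `k .. k + window - 1`.
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate in Hz.
#' @param window_ms Window length in milliseconds (default 250).
#' @return Numeric vector of length `length(x) - window + 1`.
#' @examples
#' sliding_rms(rep(2, 1000), 1000)[1]
#' @export
sliding_rms <- function(x, sampling_rate, window_ms = 250) {
  w <- round(window_ms / 1000 * sampling_rate)
  n <- length(x)
  if (w < 1 || n < w) {
    abort("Signal shorter than the RMS window.", class = "emg_parameter_error")
  }
  cs <- cumsum(c(0, x^2))
  sqrt(pmax(0, (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w))
}

#' Locate the maximal voluntary torque peak
#'
#' Automated stand-in for manual peak identification: the torque trace is
#' smoothed with a zero-phase 10 Hz low-pass, the smoothed maximum located
#' (ties resolved to the earliest sample), and the reported value is the
#' raw torque maximum within +/-50 ms of that location.
#'
#' @param torque Numeric torque series.
#' @param sampling_rate Sampling rate in Hz.
#' @return A list with `index`, `value` and `time` (s).  A constant trace
#'   triggers a degenerate-input warning and returns the mid-signal index.
#' @export
find_mvc_peak <- function(torque, sampling_rate) {
  n <- length(torque)
  if (n == 0) abort("Empty torque series.", class = "emg_parameter_error")
  if (sd(torque) == 0) {
    warn("Constant torque trace; returning mid-signal index.",
         class = "emg_degenerate_input")
    i <- (n + 1) %/% 2
    return(list(index = i, value = torque[i], time = (i - 1) / sampling_rate))
  }
  # exact ties of the raw maximum resolve to the earliest sample
  raw_max_at <- which(torque == max(torque))
  if (length(raw_max_at) > 1) {
    i <- raw_max_at[1]
    return(list(index = i, value = torque[i], time = (i - 1) / sampling_rate))
  }
  sm <- torque
  if (n > 30 && 10 < sampling_rate / 2) {
    bf <- signal::butter(2, 10 / (sampling_rate / 2), type = "low")
    sm <- as.numeric(signal::filtfilt(bf, torque))
  }
  i_sm <- which.max(sm)  # earliest maximum on ties
  half <- round(0.05 * sampling_rate)
  lo <- max(1, i_sm - half); hi <- min(n, i_sm + half)
  local <- torque[lo:hi]
  i_raw <- lo + which.max(local) - 1L
  list(index = i_raw, value = torque[i_raw],
       time = (i_raw - 1) / sampling_rate)
}

new_analysis_window <- function(data, start_time, source, sampling_rate) {
  structure(list(data = tibble::as_tibble(data), start_time = start_time,
                 source = source, sampling_rate = sampling_rate),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window> %s: [%.3f, %.3f) s, %d samples @ %g Hz\n",
              x$source, x$start_time,
              x$start_time + nrow(x$data) / x$sampling_rate,
              nrow(x$data), x$sampling_rate))
  invisible(x)
}

#' Extract the 1 s analysis window of a maximal contraction
#'
#' Returns one second of every recorded series centered on the maximal
#' voluntary torque peak (0.5 s on each side).  When the peak sits closer
#' than 0.5 s to a trial edge the window is clamped inside the trial with
#' a warning.
#'
#' @param trial An [emg_trial()].
#' @return An `analysis_window` holding `round(sampling_rate)` samples of
#'   torque and raw EMG, plus `start_time` and `source = "mvc-centered"`.
#' @export
extract_mvc_window <- function(trial) {
  stopifnot(inherits(trial, "emg_trial"))
  fs <- trial$sampling_rate
  n <- nrow(trial$data)
  w <- round(fs)
  if (n < w) abort("Trial shorter than 1 s.", class = "emg_extraction_error")
  peak <- find_mvc_peak(trial$data$torque, fs)
  start <- peak$index - round(0.5 * fs)
  clamped <- FALSE
  if (start < 1) { start <- 1L; clamped <- TRUE }
  if (start + w - 1 > n) { start <- n - w + 1L; clamped <- TRUE }
  if (clamped) {
    warn("MVC window clamped to trial bounds.", class = "emg_window_clamped")
  }
  new_analysis_window(trial$data[start:(start + w - 1L), ],
                      start_time = (start - 1) / fs,
                      source = "mvc-centered", sampling_rate = fs)
}

#' Extract the submaximal plateau window
#'
#' Returns the raw samples between seconds 3 and 4 of the trial, the
#' plateau segment of the emulated 5 s submaximal contraction.
#'
#' @param trial An [emg_trial()].
#' @return An `analysis_window` with `source = "submax-plateau"`.
#' @export
extract_submax_window <- function(trial) {
  stopifnot(inherits(trial, "emg_trial"))
  fs <- trial$sampling_rate
  n <- nrow(trial$data)
  start <- round(3 * fs) + 1L
  w <- round(fs)
  if (n < start + w - 1L) {
    abort("Trial too short for the 3-4 s plateau window.",
          class = "emg_extraction_error")
  }
  new_analysis_window(trial$data[start:(start + w - 1L), ],
                      start_time = 3, source = "submax-plateau",
                      sampling_rate = fs)
}

#' Summarize a torque or EMG window
#'
#' For maximal contractions the summary is the maximum (peak torque; peak
#' of the 250 ms sliding RMS for EMG); for submaximal contractions it is
#' the mean (mean torque; mean sliding RMS).  EMG series are expected to be
#' band-pass filtered before this step.
#'
#' @param window An `analysis_window`.
#' @param channel Column to summarize (`"torque"` or an `emg_*` column).
#' @param kind `"maximal"` or `"submaximal"`.
#' @param rms_window_ms Sliding RMS window for EMG channels.
#' @return A single numeric summary.
#' @export
summarize_window <- function(window, channel, kind = c("maximal", "submaximal"),
                             rms_window_ms = 250) {
  kind <- match.arg(kind)
  stopifnot(inherits(window, "analysis_window"))
  x <- window$data[[channel]]
  if (is.null(x)) abort(paste0("No channel `", channel, "` in window."),
                        class = "emg_parameter_error")
  if (channel == "torque") {
    return(if (kind == "maximal") max(x) else mean(x))
  }
  r <- sliding_rms(x, window$sampling_rate, rms_window_ms)
  if (kind == "maximal") max(r) else mean(r)
}
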