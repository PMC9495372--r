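#' Construct an EMG trial object
#'
#' An `emg_trial` bundles the per-sample series of one isometric contraction
#' (time, knee-flexion torque and one surface EMG channel per muscle) with
#' its sampling rate and study metadata (subject, condition, time point,
#' contraction type).
#'
#' @param data Tibble or data frame with columns `time`, `torque` and one or
#'   more `emg_<muscle>` columns (e.g. `emg_bf`, `emg_st`), all the same
#'   length.
#' @param sampling_rate Sampling rate in Hz (default 1000).
#' @param subject,condition,time_point,contraction Metadata labels.
#'   `condition` is one of `"static"`/`"neurodynamic"`, `time_point` one of
#'   `"BASELINE"`/`"WARM"`/`"STRETCH"`, `contraction` one of
#'   `"maximal"`/`"submaximal"`.  Any may be `NA` for free-standing trials.
#' @return An object of class `emg_trial`.
#' @export
emg_trial <- function(data, sampling_rate = 1000,
                      subject = NA_character_, condition = NA_character_,
                      time_point = NA_character_, contraction = NA_character_) {
  data <- tibble::as_tibble(data)
  req <- c("time", "torque")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Trial data lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "emg_format_error")
  }
  emg_cols <- grep("^emg_", names(data), value = TRUE)
  if (length(emg_cols) == 0) {
    abort("Trial data needs at least one `emg_<muscle>` column.",
          class = "emg_format_error")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be positive.", class = "emg_invalid_spec")
  }
  structure(
    list(
      data = data,
      sampling_rate = sampling_rate,
      meta = list(subject = as.character(subject),
                  condition = as.character(condition),
                  time_point = as.character(time_point),
                  contraction = as.character(contraction))
    ),
    class = "emg_trial"
  )
}

#' @export
print.emg_trial <- function(x, ...) {
  n <- nrow(x$data)
  muscles <- sub("^emg_", "", grep("^emg_", names(x$data), value = TRUE))
  cat(sprintf("<emg_trial> %d samples @ %g Hz (%.3g s), muscles: %s\n",
              n, x$sampling_rate, n / x$sampling_rate,
              paste(muscles, collapse = ", ")))
  m <- x$meta
  cat(sprintf("  subject=%s condition=%s time=%s contraction=%s\n",
              m$subject, m$condition, m$time_point, m$contraction))
  invisible(x)
}

#' @method as_tibble emg_trial
#' @export
as_tibble.emg_trial <- function(x, ...) x$data

trial_muscles <- function(trial) {
  sub("^emg_", "", grep("^emg_", names(trial$data), value = TRUE))
}

#' Generate a surrogate EMG trial
#'
#' Emulates a 5 s isometric knee-flexion contraction: the torque trace is a
#' trapezoid (0.5 s ramp up, central plateau, 0.5 s ramp down) with smooth
#' low-frequency jitter, and each EMG channel is band-limited (20-300 Hz)
#' Gaussian-type noise amplitude-modulated by the normalized torque
#' envelope.  For a submaximal contraction the plateau sits at
#' `target_fraction` of the nominal maximal torque, mimicking a tracking
#' task at 40 % of the maximal voluntary torque.
#'
#' The in-band spectral tilt of the EMG carrier is controlled by
#' `carrier_exponent`; a whiter carrier (smaller exponent) yields a more
#' irregular signal (higher sample entropy, lower DFA exponent), which is
#' how simulated cohorts inject direction-controlled complexity effects.
#'
#' @param sampling_rate Hz (default 1000).
#' @param duration Trial length in s (default 5).
#' @param contraction `"maximal"` or `"submaximal"`.
#' @param torque_plateau Nominal maximal plateau torque in N.m.
#' @param target_fraction Fraction of maximal torque targeted during
#'   submaximal contractions (default 0.4).
#' @param emg_gain EMG RMS amplitude in mV per N.m of plateau torque.
#' @param emg_band Length-2 EMG carrier band in Hz (default `c(20, 300)`).
#' @param noise_floor Baseline (rest) EMG noise RMS in mV.
#' @param torque_jitter RMS of the smoothed torque jitter in N.m.
#' @param carrier_exponent In-band spectral exponent of the EMG carrier.
#' @param seed Optional integer seed for reproducibility.
#' @param subject,condition,time_point Metadata labels passed through.
#' @return An [emg_trial()] with channels `emg_bf` and `emg_st`.
#' @examples
#' tr <- gen_emg_trial(seed = 1)
#' max(tr$data$torque)
#' @export
gen_emg_trial <- function(sampling_rate = 1000, duration = 5,
                          contraction = c("maximal", "submaximal"),
                          torque_plateau = 100, target_fraction = 0.4,
                          emg_gain = 0.01, emg_band = c(20, 300),
                          noise_floor = 0.02, torque_jitter = 1,
                          carrier_exponent = 0.5, seed = NULL,
                          subject = NA, condition = NA, time_point = NA) {
  contraction <- match.arg(contraction)
  if (target_fraction <= 0 || target_fraction >= 1) {
    abort("`target_fraction` must lie strictly between 0 and 1.",
          class = "emg_invalid_spec")
  }
  nyq <- sampling_rate / 2
  if (length(emg_band) != 2 || emg_band[1] <= 0 || emg_band[2] >= nyq ||
      emg_band[1] >= emg_band[2]) {
    abort("`emg_band` must lie strictly inside (0, Nyquist).",
          class = "emg_invalid_spec")
  }
  if (duration < 2) {
    abort("`duration` must be at least 2 s to fit the trapezoid ramps.",
          class = "emg_invalid_spec")
  }
  build <- function() {
    n <- round(duration * sampling_rate)
    t <- (seq_len(n) - 1) / sampling_rate
    ramp <- 0.5
    plateau <- torque_plateau * if (contraction == "submaximal") target_fraction else 1
    env <- pmin(1, pmin(t, duration - t) / ramp)
    env[env < 0] <- 0
    torque <- plateau * env
    # smooth (10 Hz) jitter so the trace wiggles like a human tracking task
    jit <- gen_colored_noise(n, beta = 0, band = c(0.001, 10 / sampling_rate))
    jit <- jit / sd(jit) * torque_jitter
    torque <- torque + jit * env
    frac_band <- emg_band / sampling_rate
    emg_amp <- emg_gain * plateau
    channels <- lapply(1:2, function(ch) {
      carrier <- gen_colored_noise(n, beta = carrier_exponent, band = frac_band)
      carrier <- carrier / sd(carrier)
      floor_noise <- rnorm(n, sd = noise_floor)
      carrier * env * emg_amp + floor_noise
    })
    emg_trial(
      tibble::tibble(time = t, torque = torque,
                     emg_bf = channels[[1]], emg_st = channels[[2]]),
      sampling_rate = sampling_rate,
      subject = subject, condition = condition,
      time_point = time_point, contraction = contraction
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
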