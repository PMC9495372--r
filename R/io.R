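#' Write / read a trial as delimited text with a metadata sidecar
#'
#' Trials are stored as a plain comma-separated table with a header row
#' (`time, torque, emg_<muscle>...`) plus a JSON sidecar
#' `<trial>.meta.json` holding the sampling rate and study labels.  The
#' numeric table stays parser-agnostic and the round trip reproduces the
#' series to full double precision and the metadata exactly.
#'
#' @param trial An [emg_trial()].
#' @param path Path of the CSV file to write/read.
#' @return `write_trial()` returns `path` invisibly; `read_trial()` returns
#'   an [emg_trial()].
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "emg_trial"))
  readr::write_csv(trial$data, path)
  meta <- c(trial$meta, list(sampling_rate = trial$sampling_rate))
  jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

meta_path <- function(path) paste0(tools::file_path_sans_ext(path), ".meta.json")

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Trial file not found: ", path), class = "emg_format_error")
  }
  mp <- meta_path(path)
  if (!file.exists(mp)) {
    abort(paste0("Missing metadata sidecar: ", mp), class = "emg_format_error")
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(dat)
  if (nrow(prob) > 0) {
    abort(paste0("Malformed trial file ", path, " (row ", prob$row[1],
                 ": ", prob$expected[1], " vs ", prob$actual[1], ")."),
          class = "emg_format_error")
  }
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate)) {
    abort(paste0("Metadata sidecar lacks `sampling_rate`: ", mp),
          class = "emg_format_error")
  }
  null_na <- function(x) if (is.null(x) || length(x) == 0) NA_character_ else x
  emg_trial(dat, sampling_rate = as.numeric(meta$sampling_rate),
            subject = null_na(meta$subject), condition = null_na(meta$condition),
            time_point = null_na(meta$time_point),
            contraction = null_na(meta$contraction))
}

#' Study analysis configuration
#'
#' Holds every tunable of the analysis chain with the emulated study's
#' settings as defaults: 20-300 Hz 4th-order band-pass, 250 ms sliding RMS
#' window, sample entropy with `m = 2` and `r = 0.2 x SD`, recurrence
#' analysis with delay 5, dimension 10, radius 25 % of the maximum
#' distance and minimum diagonal length 3, DFA over 40 log-spaced box sizes
#' from 4 to 251 samples, and a 0.05 significance level.
#'
#' @param ... Named overrides of the defaults (see Details).
#' @details Available keys and defaults: `sampling_rate` (1000 Hz),
#'   `filter_low` (20 Hz), `filter_high` (300 Hz), `filter_order` (4),
#'   `rms_window_ms` (250), `sampen_m` (2), `sampen_r` (0.2),
#'   `rqa_delay` (5), `rqa_dim` (10), `rqa_radius` (0.25), `rqa_lmin` (3),
#'   `dfa_box_min` (4), `dfa_box_max` (251), `dfa_n_boxes` (40),
#'   `alpha_level` (0.05).
#' @return An object of class `study_config` (a named list).
#' @examples
#' study_config()
#' study_config(rqa_delay = 8)
#' @export
study_config <- function(...) {
  defaults <- list(
    sampling_rate = 1000, filter_low = 20, filter_high = 300, filter_order = 4,
    rms_window_ms = 250, sampen_m = 2, sampen_r = 0.2,
    rqa_delay = 5, rqa_dim = 10, rqa_radius = 0.25, rqa_lmin = 3,
    dfa_box_min = 4, dfa_box_max = 251, dfa_n_boxes = 40,
    alpha_level = 0.05
  )
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    abort("All configuration overrides must be named.", class = "emg_config_error")
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    warn(paste0("Ignoring unknown configuration key(s): ",
                paste(unknown, collapse = ", ")))
    over <- over[setdiff(names(over), unknown)]
  }
  cfg <- utils::modifyList(defaults, over)
  validate_config(cfg)
  structure(cfg, class = "study_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(msg, class = "emg_config_error")
  chk(cfg$sampling_rate > 0, "`sampling_rate` must be positive.")
  chk(cfg$filter_low > 0 && cfg$filter_low < cfg$filter_high,
      "Filter band must satisfy 0 < low < high.")
  chk(cfg$filter_high < cfg$sampling_rate / 2,
      "Filter upper edge must be below the Nyquist frequency.")
  chk(cfg$filter_order >= 2 && cfg$filter_order %% 2 == 0,
      "`filter_order` must be an even integer >= 2.")
  chk(cfg$rms_window_ms > 0, "`rms_window_ms` must be positive.")
  chk(cfg$sampen_m >= 1, "`sampen_m` must be >= 1.")
  chk(cfg$sampen_r > 0, "`sampen_r` must be positive.")
  chk(cfg$rqa_delay >= 1, "`rqa_delay` must be >= 1.")
  chk(cfg$rqa_dim >= 1, "`rqa_dim` must be >= 1.")
  chk(cfg$rqa_radius > 0 && cfg$rqa_radius <= 1,
      "`rqa_radius` must lie in (0, 1].")
  chk(cfg$rqa_lmin >= 2, "`rqa_lmin` must be >= 2.")
  chk(cfg$dfa_box_min >= 4 && cfg$dfa_box_min < cfg$dfa_box_max,
      "DFA box sizes must satisfy 4 <= box_min < box_max.")
  chk(cfg$dfa_n_boxes >= 2, "`dfa_n_boxes` must be >= 2.")
  chk(cfg$alpha_level > 0 && cfg$alpha_level < 1,
      "`alpha_level` must lie in (0, 1).")
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (k in names(x)) cat(sprintf("  %-14s %g\n", k, x[[k]]))
  invisible(x)
}

#' Load a study configuration from a JSON file
#'
#' Reads a flat key-value JSON object; keys not present fall back to the
#' [study_config()] defaults.  Unknown keys raise a warning, out-of-range
#' values a configuration error.
#'
#' @param path Path to a JSON file; an empty or absent-key file yields the
#'   full default configuration.
#' @return A `study_config`.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0) return(study_config())
  do.call(study_config, as.list(raw))
}
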