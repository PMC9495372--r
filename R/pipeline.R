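#' Analyze one trial: amplitude and complexity metrics per muscle
#'
#' Reproduces the per-trial analysis chain: each EMG channel is band-pass
#' filtered over the full trial, the 1 s analysis window is extracted
#' (centered on the maximal voluntary torque peak for maximal contractions,
#' seconds 3-4 of the plateau for submaximal ones), and per muscle the
#' sliding-RMS summary, sample entropy, recurrence measures (%Rec, %Det)
#' and DFA exponent are computed on the filtered window.  The torque
#' summary is the raw peak torque (maximal) or the window mean
#' (submaximal).
#'
#' @param trial An [emg_trial()].
#' @param config A [study_config()] (defaults used when omitted).
#' @return A tibble with one row per muscle and columns `subject`,
#'   `condition`, `time`, `contraction`, `muscle`, `peak_torque`,
#'   `torque`, `rms`, `sampen`, `pct_rec`, `pct_det`, `alpha`, plus a
#'   `degenerate` flag raised when any metric hit a degenerate-input
#'   condition.
#' @examples
#' tr <- gen_emg_trial(seed = 3)
#' analyze_trial(tr)
#' @export
analyze_trial <- function(trial, config = study_config()) {
  stopifnot(inherits(trial, "emg_trial"))
  kind <- trial$meta$contraction
  if (is.na(kind) || !kind %in% c("maximal", "submaximal")) {
    abort("Trial metadata must state contraction type (maximal/submaximal).",
          class = "emg_parameter_error")
  }
  fs <- trial$sampling_rate
  muscles <- trial_muscles(trial)
  filtered <- trial
  for (m in muscles) {
    col <- paste0("emg_", m)
    filtered$data[[col]] <- bandpass_filter(
      trial$data[[col]], fs, low = config$filter_low,
      high = config$filter_high, order = config$filter_order
    )
  }
  win <- tryCatch(
    if (kind == "maximal") extract_mvc_window(filtered)
    else extract_submax_window(filtered),
    error = function(e) {
      abort(paste0("Trial ", trial$meta$subject, "/", trial$meta$condition,
                   "/", trial$meta$time_point, " (", kind, "): ",
                   conditionMessage(e)),
            class = "emg_extraction_error")
    }
  )
  peak <- if (kind == "maximal") {
    suppressWarnings(find_mvc_peak(trial$data$torque, fs)$value)
  } else {
    NA_real_
  }
  torque_summary <- summarize_window(win, "torque", kind)
  purrr::map_dfr(muscles, function(m) {
    x <- win$data[[paste0("emg_", m)]]
    degenerate <- FALSE
    note_degenerate <- function(expr) {
      withCallingHandlers(expr, warning = function(w) {
        if (inherits(w, "emg_degenerate_input")) {
          degenerate <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    }
    rms_val <- summarize_window(win, paste0("emg_", m), kind,
                                rms_window_ms = config$rms_window_ms)
    se <- sample_entropy(x, m = config$sampen_m, r_fraction = config$sampen_r)
    rq <- note_degenerate(rqa(x, dim = config$rqa_dim, delay = config$rqa_delay,
                              radius_fraction = config$rqa_radius,
                              l_min = config$rqa_lmin))
    df_res <- suppressWarnings(
      dfa(x, box_min = config$dfa_box_min, box_max = config$dfa_box_max,
          n_boxes = config$dfa_n_boxes)
    )
    tibble::tibble(
      subject = trial$meta$subject, condition = trial$meta$condition,
      time = trial$meta$time_point, contraction = kind, muscle = m,
      peak_torque = peak, torque = torque_summary, rms = rms_val,
      sampen = se$value, pct_rec = rq$pct_rec, pct_det = rq$pct_det,
      alpha = df_res$alpha,
      degenerate = degenerate || se$flag != "ok" || rq$degenerate
    )
  })
}

#' Assemble the long cohort table from per-trial metrics
#'
#' Keeps, per subject x condition x time x contraction cell, the maximal
#' trial with the highest peak torque (the "best contraction"; ties keep
#' the first), then pivots the metrics into the long
#' subject/condition/time/variable/value layout consumed by the
#' statistics layer.  Variable names are `torque` and
#' `<metric>_<muscle>` (e.g. `sampen_bf`), yielding 11 variables for two
#' muscles.
#'
#' @param metrics Tibble of rows from [analyze_trial()] (stacked).
#' @return A tibble with columns `subject`, `condition`, `time`,
#'   `contraction`, `variable`, `value`.
#' @export
assemble_cohort_table <- function(metrics) {
  best <- metrics |>
    dplyr::group_by(.data$subject, .data$condition, .data$time,
                    .data$contraction, .data$muscle) |>
    dplyr::slice(if (all(is.na(.data$peak_torque))) 1L
                 else which.max(.data$peak_torque)) |>
    dplyr::ungroup()
  long <- best |>
    tidyr::pivot_longer(cols = c("rms", "sampen", "pct_rec", "pct_det", "alpha"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(variable = paste0(.data$metric, "_", .data$muscle)) |>
    dplyr::select("subject", "condition", "time", "contraction",
                  "variable", "value")
  torque <- best |>
    dplyr::distinct(.data$subject, .data$condition, .data$time,
                    .data$contraction, .data$torque) |>
    dplyr::mutate(variable = "torque") |>
    dplyr::rename(value = "torque")
  dplyr::bind_rows(torque, long) |>
    dplyr::arrange(.data$contraction, .data$variable, .data$subject,
                   .data$condition, .data$time)
}

#' Run the full study analysis
#'
#' Orchestrates trials -> windows -> metrics -> cohort table -> statistics:
#' analyzes every trial, retains the best maximal contraction per cell,
#' runs the two-way repeated-measures ANOVA per variable and contraction
#' type, and computes Bonferroni post hocs for every significant main
#' effect or interaction.  Optionally writes the ANOVA table, post hocs
#' and metrics as CSV files.
#'
#' @param trials List of [emg_trial()] objects, or a manifest tibble with
#'   a `path` column pointing at trial files written by [write_trial()].
#' @param config A [study_config()].
#' @param out_dir Optional directory for `metrics.csv`, `anova.csv` and
#'   `posthoc.csv`.
#' @return A list of class `emg_study` with `metrics`, `cohort_table`,
#'   `anova` (tibble: contraction, variable, effect, df1, df2, f, p,
#'   epsilon_gg, partial_eta_sq, ...), and `posthoc`.
#' @export
run_study <- function(trials, config = study_config(), out_dir = NULL) {
  if (is.data.frame(trials)) {
    if (!"path" %in% names(trials)) {
      abort("Manifest must have a `path` column.", class = "emg_format_error")
    }
    trials <- lapply(trials$path, read_trial)
  }
  metrics <- purrr::map_dfr(trials, analyze_trial, config = config)
  cohort <- assemble_cohort_table(metrics)

  combos <- dplyr::distinct(cohort, .data$contraction, .data$variable)
  anova_tab <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    sub <- cohort[cohort$contraction == combos$contraction[i] &
                    cohort$variable == combos$variable[i], ]
    res <- tidy(rm_anova_2way(sub, alpha_level = config$alpha_level))
    dplyr::bind_cols(
      tibble::tibble(contraction = combos$contraction[i],
                     variable = combos$variable[i]),
      res
    )
  })
  sig <- anova_tab[!is.na(anova_tab$p) & anova_tab$p < config$alpha_level &
                     anova_tab$effect %in% c("condition", "time"), ]
  posthoc <- purrr::map_dfr(seq_len(nrow(sig)), function(i) {
    sub <- cohort[cohort$contraction == sig$contraction[i] &
                    cohort$variable == sig$variable[i], ]
    ph <- bonferroni_posthoc(sub, factor = sig$effect[i])
    dplyr::bind_cols(
      tibble::tibble(contraction = sig$contraction[i],
                     variable = sig$variable[i], effect = sig$effect[i]),
      ph
    )
  })
  out <- structure(list(metrics = metrics, cohort_table = cohort,
                        anova = anova_tab, posthoc = posthoc,
                        config = config),
                   class = "emg_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"))
    readr::write_csv(anova_tab, file.path(out_dir, "anova.csv"))
    readr::write_csv(posthoc, file.path(out_dir, "posthoc.csv"))
  }
  out
}

#' @export
print.emg_study <- function(x, ...) {
  cat(sprintf("<emg_study> %d trials analyzed, %d variables x %d effects\n",
              length(unique(paste(x$metrics$subject, x$metrics$condition,
                                  x$metrics$time, x$metrics$contraction))),
              length(unique(x$anova$variable)),
              length(unique(x$anova$effect))))
  n_sig <- sum(x$anova$p < x$config$alpha_level, na.rm = TRUE)
  cat(sprintf("  %d significant effect(s) at alpha = %g; %d post hoc row(s)\n",
              n_sig, x$config$alpha_level,
              nrow(x$posthoc)))
  invisible(x)
}

#' @method tidy emg_study
#' @export
tidy.emg_study <- function(x, ...) x$anova

#' @method glance emg_study
#' @export
glance.emg_study <- function(x, ...) {
  tibble::tibble(
    n_trials = nrow(dplyr::distinct(x$metrics, .data$subject, .data$condition,
                                    .data$time, .data$contraction)),
    n_variables = length(unique(x$anova$variable)),
    n_significant = sum(x$anova$p < x$config$alpha_level, na.rm = TRUE)
  )
}

#' Plot cohort-level metric summaries
#'
#' Mean and standard deviation of one variable across time points, by
#' condition — the standard summary figure for a 2 x 3 within-subject
#' design.
#'
#' @param study An `emg_study` from [run_study()].
#' @param variable Variable name (e.g. `"sampen_bf"`).
#' @param contraction `"maximal"` or `"submaximal"`.
#' @return A ggplot object.
#' @export
plot_cohort_summary <- function(study, variable,
                                contraction = c("maximal", "submaximal")) {
  contraction <- match.arg(contraction)
  df <- study$cohort_table
  df <- df[df$variable == variable & df$contraction == contraction, ]
  if (nrow(df) == 0) {
    abort("No rows for that variable/contraction.", class = "emg_parameter_error")
  }
  canon <- c("BASELINE", "WARM", "STRETCH")
  df$time <- factor(df$time, levels = canon[canon %in% unique(df$time)])
  summ <- df |>
    dplyr::group_by(.data$condition, .data$time) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$time, y = .data$mean,
                                     group = .data$condition,
                                     color = .data$condition)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15,
                           position = ggplot2::position_dodge(0.2)) +
    ggplot2::labs(x = NULL, y = variable,
                  title = paste0(variable, " (", contraction, ")")) +
    ggplot2::theme_minimal()
}
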