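#' Simulate a cohort-level measurement table
#'
#' Draws a balanced subject x condition x time table of values for one or
#' more variables from an additive random-effects model: each subject has a
#' Gaussian baseline (SD `between_sd`), each cell adds independent Gaussian
#' within-subject noise (SD `within_sd`), and the effect map adds fixed
#' shifts at chosen time points.  This is the ground-truth model the
#' repeated-measures statistical layer is calibrated against (type-I error
#' and power), without going through signal synthesis.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param variables Character vector of variable names.
#' @param conditions,times Factor levels (defaults: static/neurodynamic and
#'   BASELINE/WARM/STRETCH).
#' @param effect_map Named list: for each variable, a named numeric vector
#'   of additive shifts at given time points, in units of `between_sd`
#'   (e.g. `list(sampen = c(WARM = 1, STRETCH = 1))`).
#' @param grand_mean,between_sd,within_sd Scalars or named vectors per
#'   variable.
#' @param seed Optional integer seed.
#' @return A tibble with columns `subject`, `condition`, `time`, `variable`,
#'   `value` — one row per cell, a complete balanced crossing.
#' @examples
#' tab <- simulate_cohort_table(seed = 1)
#' dplyr::count(tab, condition, time)
#' @export
simulate_cohort_table <- function(n_subjects = 16, variables = "y",
                                  conditions = c("static", "neurodynamic"),
                                  times = c("BASELINE", "WARM", "STRETCH"),
                                  effect_map = list(), grand_mean = 0,
                                  between_sd = 1, within_sd = 0.5,
                                  seed = NULL) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2.", class = "emg_invalid_spec")
  get_par <- function(par, v) {
    if (length(par) == 1 && is.null(names(par))) return(unname(par))
    unname(par[[v]] %||% abort(paste0("No value of parameter for variable ", v),
                               class = "emg_invalid_spec"))
  }
  build <- function() {
    purrr::map_dfr(variables, function(v) {
      mu <- get_par(grand_mean, v)
      b <- get_par(between_sd, v)
      w <- get_par(within_sd, v)
      shifts <- effect_map[[v]] %||% numeric(0)
      baseline <- rnorm(n_subjects, mu, b)
      grid <- tidyr::expand_grid(
        subject = sprintf("S%02d", seq_len(n_subjects)),
        condition = conditions, time = times
      )
      grid$value <- baseline[match(grid$subject, sprintf("S%02d", seq_len(n_subjects)))] +
        b * unname(ifelse(grid$time %in% names(shifts),
                          shifts[grid$time], 0)) +
        rnorm(nrow(grid), 0, w)
      grid$variable <- v
      grid[, c("subject", "condition", "time", "variable", "value")]
    })
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Generate a simulated study cohort of EMG trials
#'
#' Produces the full balanced design of the emulated study — `n_subjects`
#' subjects x 2 stretching conditions x 3 time points x 2 contraction types
#' — as surrogate EMG trials, together with a manifest and a ground-truth
#' table of the injected effects.
#'
#' Subject heterogeneity enters through per-subject maximal torque and EMG
#' carrier tilt baselines.  Effects requested in `effect_map` are injected
#' at two levels: `torque` shifts move the plateau torque (in units of the
#' between-subject torque SD), and `sampen` shifts whiten the EMG carrier
#' at the shifted time points (raising measured sample entropy and lowering
#' the DFA exponent).  All injected shifts are recorded in the returned
#' `truth` table so recovery can be checked against ground truth.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param conditions,times Factor levels as in [simulate_cohort_table()].
#' @param effect_map Named list of time-point shifts, e.g.
#'   `list(torque = c(WARM = 0.5), sampen = c(WARM = 1, STRETCH = 1))`.
#' @param torque_mean,torque_between_sd Population mean and between-subject
#'   SD of maximal plateau torque (N.m).
#' @param carrier_exponent_mean,carrier_exponent_sd Population mean and
#'   between-subject SD of the EMG carrier spectral exponent.
#' @param sampen_beta_slope Change in carrier exponent per unit injected
#'   `sampen` shift (negative: whiter carrier at shifted time points).
#' @param n_maximal Maximal-contraction repeats per cell (default 1; set 2
#'   to emulate the protocol's two attempts, of which the analysis retains
#'   the one with the higher peak torque).
#' @param seed Integer seed (default 1); sub-seeds per trial are derived
#'   deterministically.
#' @param ... Further arguments passed to [gen_emg_trial()].
#' @return A list with `trials` (list of [emg_trial()]), `manifest` (tibble:
#'   subject, condition, time, contraction, trial index) and `truth`
#'   (tibble of injected per-cell shifts per variable).
#' @export
gen_cohort <- function(n_subjects = 16,
                       conditions = c("static", "neurodynamic"),
                       times = c("BASELINE", "WARM", "STRETCH"),
                       effect_map = list(),
                       torque_mean = 100, torque_between_sd = 15,
                       carrier_exponent_mean = 0.5, carrier_exponent_sd = 0.08,
                       sampen_beta_slope = -0.3, n_maximal = 1,
                       seed = 1, ...) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2.", class = "emg_invalid_spec")
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  base_torque <- withr::with_seed(derive_seed(seed, 1),
                                  rnorm(n_subjects, torque_mean, torque_between_sd))
  base_beta <- withr::with_seed(derive_seed(seed, 2),
                                rnorm(n_subjects, carrier_exponent_mean, carrier_exponent_sd))
  torque_shift <- effect_map[["torque"]] %||% numeric(0)
  sampen_shift <- effect_map[["sampen"]] %||% numeric(0)

  design <- tidyr::expand_grid(subject = subjects, condition = conditions,
                               time = times)
  trials <- list()
  manifest <- list()
  k <- 0L
  for (i in seq_len(nrow(design))) {
    s <- design$subject[i]; cnd <- design$condition[i]; tm <- design$time[i]
    si <- match(s, subjects)
    plateau <- base_torque[si] +
      torque_between_sd * (if (tm %in% names(torque_shift)) torque_shift[[tm]] else 0)
    beta <- base_beta[si] +
      sampen_beta_slope * (if (tm %in% names(sampen_shift)) sampen_shift[[tm]] else 0)
    reps <- c(rep("maximal", n_maximal), "submaximal")
    for (j in seq_along(reps)) {
      k <- k + 1L
      trials[[k]] <- gen_emg_trial(
        contraction = reps[j], torque_plateau = plateau,
        carrier_exponent = max(-1, beta),
        seed = derive_seed(seed, 1000L + k),
        subject = s, condition = cnd, time_point = tm, ...
      )
      manifest[[k]] <- tibble::tibble(
        subject = s, condition = cnd, time = tm,
        contraction = reps[j], trial = k
      )
    }
  }
  truth <- purrr::map_dfr(names(effect_map), function(v) {
    sh <- effect_map[[v]]
    tidyr::expand_grid(variable = v, time = times) |>
      dplyr::mutate(shift = ifelse(.data$time %in% names(sh), sh[.data$time], 0))
  })
  list(trials = trials, manifest = dplyr::bind_rows(manifest), truth = truth)
}
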