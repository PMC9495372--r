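#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, the proportion of effect-plus-
#' error variance attributable to the effect.  Conventional descriptors:
#' 0.01 small, 0.06 medium, above 0.14 large.
#'
#' @param f F statistic (vectorized).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Numeric vector of partial eta squared values in `[0, 1]`.
#' @examples
#' partial_eta_sq(11.942, 2, 30)
#' @export
partial_eta_sq <- function(f, df1, df2) {
  if (any(f < 0) || any(df1 <= 0) || any(df2 <= 0)) {
    abort("Need f >= 0 and positive degrees of freedom.",
          class = "emg_parameter_error")
  }
  f * df1 / (f * df1 + df2)
}

#' Cohen's d for paired samples
#'
#' Standardized mean difference.  The default (`method = "differences"`)
#' divides the mean paired difference by the SD of the differences; the
#' alternative (`method = "pooled"`) divides by the pooled SD of the two
#' level distributions.  Which convention a given report used is often
#' unstated, so both are available.  Descriptors follow the thresholds
#' |d| < 0.5 small, 0.5 <= |d| <= 1.2 medium, |d| > 1.2 large.
#'
#' @param x,y Paired numeric vectors (same length, same subjects in the
#'   same order), or `y = NULL` with `x` already the vector of paired
#'   differences.
#' @param method `"differences"` (default) or `"pooled"`.
#' @return A list with `d` and `descriptor`.
#' @examples
#' cohens_d(c(3, 4, 5, 6), c(2, 2, 4, 5))
#' @export
cohens_d <- function(x, y = NULL, method = c("differences", "pooled")) {
  method <- match.arg(method)
  if (is.null(y)) {
    diffs <- x
    if (method == "pooled") {
      abort("`method = \"pooled\"` needs both `x` and `y`.",
            class = "emg_parameter_error")
    }
  } else {
    if (length(x) != length(y)) {
      abort("`x` and `y` must have equal length (paired).",
            class = "emg_parameter_error")
    }
    diffs <- x - y
  }
  denom <- if (method == "differences") sd(diffs)
           else sqrt((stats::var(x) + stats::var(y)) / 2)
  if (!is.finite(denom) || denom == 0) {
    return(list(d = NA_real_, descriptor = "undefined"))
  }
  d <- mean(diffs) / denom
  list(d = d, descriptor = d_descriptor(d))
}

d_descriptor <- function(d) {
  ad <- abs(d)
  if (ad < 0.5) "small" else if (ad <= 1.2) "medium" else "large"
}

# --- internal: contrast machinery for the within-subject design ----------

# orthonormal contrasts for a k-level factor (k-1 columns)
orthonormal_contrasts <- function(k) {
  c_raw <- stats::contr.helmert(k)
  qr.Q(qr(c_raw))[, seq_len(k - 1), drop = FALSE]
}

# cell matrix: one row per subject, one column per condition:time cell
cell_matrix <- function(df, conditions, times) {
  subjects <- sort(unique(df$subject))
  m <- matrix(NA_real_, length(subjects),
              length(conditions) * length(times),
              dimnames = list(subjects, NULL))
  idx <- 0L
  for (cn in conditions) for (tm in times) {
    idx <- idx + 1L
    v <- df$value[df$condition == cn & df$time == tm]
    m[, idx] <- v[match(subjects, df$subject[df$condition == cn & df$time == tm])]
  }
  m
}

# Greenhouse-Geisser epsilon and Mauchly test from the covariance of
# orthonormal within-subject contrast scores (p = #contrasts, n subjects)
gg_mauchly <- function(scores) {
  p <- ncol(scores)
  n <- nrow(scores)
  s <- stats::cov(scores)
  eps <- sum(diag(s))^2 / (p * sum(s^2))
  if (p < 2 || n <= p) {
    return(list(epsilon = eps, mauchly_w = NA_real_, mauchly_p = NA_real_))
  }
  w <- det(s) / (sum(diag(s)) / p)^p
  if (!is.finite(w) || w <= 0) {
    return(list(epsilon = eps, mauchly_w = w, mauchly_p = NA_real_))
  }
  df_chi <- p * (p + 1) / 2 - 1
  chi <- -(n - 1 - (2 * p^2 + p + 2) / (6 * p)) * log(w)
  list(epsilon = eps, mauchly_w = w,
       mauchly_p = stats::pchisq(chi, df_chi, lower.tail = FALSE))
}

check_balanced <- function(df) {
  counts <- dplyr::count(df, .data$subject, .data$condition, .data$time)
  n_cells <- length(unique(df$condition)) * length(unique(df$time))
  bad <- dplyr::count(counts, .data$subject)$n != n_cells
  if (any(counts$n != 1) || any(bad)) {
    grid <- tidyr::expand_grid(subject = unique(df$subject),
                               condition = unique(df$condition),
                               time = unique(df$time))
    missing_cells <- dplyr::anti_join(grid, df,
                                      by = c("subject", "condition", "time"))
    abort(paste0("Design is not a complete balanced crossing; ",
                 nrow(missing_cells), " missing cell(s), e.g. ",
                 paste(utils::head(apply(missing_cells, 1, paste, collapse = "/"), 3),
                       collapse = ", ")),
          class = "emg_design_error")
  }
  invisible(df)
}

#' Two-way repeated-measures ANOVA (condition x time)
#'
#' Fully within-subject two-way ANOVA: each effect (condition, time,
#' condition x time) is tested against its own subject-by-effect
#' interaction error term.  Sphericity of each within-subject effect with
#' more than one degree of freedom is assessed with Mauchly's test on the
#' covariance of orthonormal contrast scores; when that test rejects at
#' `alpha_level`, the Greenhouse-Geisser epsilon rescales both degrees of
#' freedom of the F test.  Partial eta squared is reported per effect.
#'
#' @param table Long-format tibble with columns `subject`, `condition`,
#'   `time`, `value` — and optionally `variable`, filtered by the
#'   `variable` argument.  The design must be complete and balanced (one
#'   value per subject x condition x time cell); missing cells are an
#'   error, never imputed.
#' @param variable When `table` holds several variables, which one to
#'   analyze.
#' @param alpha_level Significance level used to decide whether the
#'   Greenhouse-Geisser correction is applied (default 0.05).
#' @return An object of class `emg_anova`; its `tidy()` method returns a
#'   tibble with one row per effect: `effect`, `df1`, `df2`, `f`,
#'   `p_uncorrected`, `epsilon_gg`, `mauchly_p`, `gg_applied`, `p`
#'   (corrected where applied) and `partial_eta_sq`.
#' @examples
#' tab <- simulate_cohort_table(n_subjects = 8, seed = 2)
#' tidy(rm_anova_2way(tab))
#' @export
rm_anova_2way <- function(table, variable = NULL, alpha_level = 0.05) {
  df <- tibble::as_tibble(table)
  if (!is.null(variable)) df <- df[df$variable == variable, ]
  if ("variable" %in% names(df) && length(unique(df$variable)) > 1) {
    abort("Several variables present; pick one with `variable`.",
          class = "emg_parameter_error")
  }
  req <- c("subject", "condition", "time", "value")
  if (!all(req %in% names(df))) {
    abort("Table needs columns subject, condition, time, value.",
          class = "emg_format_error")
  }
  if (length(unique(df$subject)) < 2) {
    abort("Need at least 2 subjects.", class = "emg_design_error")
  }
  check_balanced(df)
  conditions <- sort(unique(df$condition))
  times <- unique(df$time)
  # keep the natural ordering BASELINE/WARM/STRETCH when present
  canon <- c("BASELINE", "WARM", "STRETCH")
  times <- if (all(times %in% canon)) canon[canon %in% times] else sort(times)

  df$condition <- factor(df$condition, levels = conditions)
  df$time <- factor(df$time, levels = times)
  df$subject <- factor(df$subject)

  fit <- aov(value ~ condition * time + Error(subject / (condition * time)),
             data = df)
  sm <- summary(fit)
  pull_row <- function(stratum, term) {
    tab <- sm[[paste0("Error: ", stratum)]][[1]]
    i <- which(trimws(rownames(tab)) == term)
    err <- which(trimws(rownames(tab)) == "Residuals")
    list(f = tab[i, "F value"], df1 = tab[i, "Df"], df2 = tab[err, "Df"],
         p = tab[i, "Pr(>F)"])
  }
  rows <- list(
    condition = pull_row("subject:condition", "condition"),
    time = pull_row("subject:time", "time"),
    `condition:time` = pull_row("subject:condition:time", "condition:time")
  )

  # sphericity per effect, from the subject x cell matrix
  cm <- cell_matrix(df, conditions, times)
  nc <- length(conditions); nt <- length(times)
  ccond <- orthonormal_contrasts(nc)
  ctime <- orthonormal_contrasts(nt)
  ones_c <- rep(1 / sqrt(nc), nc)
  ones_t <- rep(1 / sqrt(nt), nt)
  eff_contrasts <- list(
    condition = kronecker(ccond, matrix(ones_t, ncol = 1)),
    time = kronecker(matrix(ones_c, ncol = 1), ctime),
    `condition:time` = kronecker(ccond, ctime)
  )
  out <- purrr::map_dfr(names(rows), function(eff) {
    r <- rows[[eff]]
    contr <- eff_contrasts[[eff]]
    sph <- if (ncol(contr) < 2) {
      list(epsilon = 1, mauchly_w = NA_real_, mauchly_p = NA_real_)
    } else {
      gg_mauchly(cm %*% contr)
    }
    gg_applied <- is.finite(sph$mauchly_p) && sph$mauchly_p < alpha_level
    p_corr <- if (gg_applied) {
      pf(r$f, r$df1 * sph$epsilon, r$df2 * sph$epsilon, lower.tail = FALSE)
    } else {
      r$p
    }
    tibble::tibble(
      effect = eff, df1 = r$df1, df2 = r$df2, f = r$f,
      p_uncorrected = r$p, epsilon_gg = sph$epsilon,
      mauchly_p = sph$mauchly_p, gg_applied = gg_applied, p = p_corr,
      partial_eta_sq = partial_eta_sq(r$f, r$df1, r$df2)
    )
  })
  structure(list(table = out,
                 variable = variable %||% NA_character_,
                 n_subjects = nrow(cm), alpha_level = alpha_level),
            class = "emg_anova")
}

#' @export
print.emg_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA (%d subjects%s)\n",
              x$n_subjects,
              if (!is.na(x$variable)) paste0(", variable: ", x$variable) else ""))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @method tidy emg_anova
#' @export
tidy.emg_anova <- function(x, ...) x$table

#' @method glance emg_anova
#' @export
glance.emg_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 alpha_level = x$alpha_level,
                 n_significant = sum(x$table$p < x$alpha_level, na.rm = TRUE))
}

#' Bonferroni-corrected pairwise post hoc comparisons
#'
#' All pairwise paired t-tests between the levels of one within-subject
#' factor, with per-subject values averaged over the other factor
#' (marginal means).  Adjusted p-values are `min(1, p * n_pairs)`; the
#' 95 % confidence interval of the mean difference comes from the paired-t
#' distribution; Cohen's d follows [cohens_d()].
#'
#' @inheritParams rm_anova_2way
#' @param factor `"time"` or `"condition"`.
#' @param conf_level Confidence level for the mean-difference interval.
#' @param d_method Passed to [cohens_d()].
#' @return A tibble with one row per pair: `level_1`, `level_2`,
#'   `mean_difference`, `conf_low`, `conf_high`, `p`, `p_adjusted`,
#'   `cohens_d`, `descriptor`.
#' @export
bonferroni_posthoc <- function(table, variable = NULL,
                               factor = c("time", "condition"),
                               conf_level = 0.95,
                               d_method = c("differences", "pooled")) {
  factor <- match.arg(factor)
  d_method <- match.arg(d_method)
  df <- tibble::as_tibble(table)
  if (!is.null(variable)) df <- df[df$variable == variable, ]
  check_balanced(df)
  other <- if (factor == "time") "condition" else "time"
  marg <- df |>
    dplyr::group_by(.data$subject, .data[[factor]]) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  levels_f <- unique(df[[factor]])
  canon <- c("BASELINE", "WARM", "STRETCH")
  levels_f <- if (all(levels_f %in% canon)) canon[canon %in% levels_f]
              else sort(levels_f)
  if (length(levels_f) < 2) {
    abort("Factor needs at least 2 levels.", class = "emg_parameter_error")
  }
  pairs <- utils::combn(levels_f, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  purrr::map_dfr(pairs, function(pr) {
    a <- marg$value[marg[[factor]] == pr[1]][order(marg$subject[marg[[factor]] == pr[1]])]
    b <- marg$value[marg[[factor]] == pr[2]][order(marg$subject[marg[[factor]] == pr[2]])]
    diffs <- a - b
    if (sd(diffs) == 0) {
      warn(paste0("Zero variance of paired differences for ", pr[1], " vs ",
                  pr[2], "; p undefined."), class = "emg_degenerate_input")
      return(tibble::tibble(level_1 = pr[1], level_2 = pr[2],
                            mean_difference = mean(diffs),
                            conf_low = mean(diffs), conf_high = mean(diffs),
                            p = NA_real_, p_adjusted = NA_real_,
                            cohens_d = NA_real_, descriptor = "undefined"))
    }
    tt <- t.test(a, b, paired = TRUE, conf.level = conf_level)
    dd <- if (d_method == "differences") cohens_d(diffs)
          else cohens_d(a, b, method = "pooled")
    tibble::tibble(
      level_1 = pr[1], level_2 = pr[2],
      mean_difference = unname(tt$estimate),
      conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
      p = tt$p.value, p_adjusted = min(1, tt$p.value * n_pairs),
      cohens_d = dd$d, descriptor = dd$descriptor
    )
  })
}

#' Normality and sphericity checks
#'
#' `check_normality()` wraps the Shapiro-Wilk test; `sphericity_test()`
#' runs Mauchly's test on the orthonormal contrast scores of one
#' within-subject factor (marginal means over the other factor).  Both
#' return a `(statistic, p)` pair, or `NA` with an explanatory `note`
#' when the test does not apply (fewer than 3 observations, or a factor
#' with fewer than 3 levels).
#'
#' @param values Numeric vector (normality).
#' @return A tibble with `statistic`, `p` and `note`.
#' @export
check_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    return(tibble::tibble(statistic = NA_real_, p = NA_real_,
                          note = "not applicable: n < 3"))
  }
  sw <- shapiro.test(values)
  tibble::tibble(statistic = unname(sw$statistic), p = sw$p.value, note = "ok")
}

#' @rdname check_normality
#' @inheritParams bonferroni_posthoc
#' @export
sphericity_test <- function(table, variable = NULL,
                            factor = c("time", "condition")) {
  factor <- match.arg(factor)
  df <- tibble::as_tibble(table)
  if (!is.null(variable)) df <- df[df$variable == variable, ]
  check_balanced(df)
  k <- length(unique(df[[factor]]))
  if (k < 3) {
    return(tibble::tibble(statistic = NA_real_, p = NA_real_,
                          note = "not applicable: fewer than 3 levels"))
  }
  other <- if (factor == "time") "condition" else "time"
  marg <- df |>
    dplyr::group_by(.data$subject, .data[[factor]]) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(factor),
                       values_from = "value")
  m <- as.matrix(marg[, -1])
  res <- gg_mauchly(m %*% orthonormal_contrasts(k))
  tibble::tibble(statistic = res$mauchly_w, p = res$mauchly_p, note = "ok")
}
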