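#' Log-spaced DFA box sizes
#'
#' Generates `n_boxes` box sizes spaced evenly on a log scale between
#' `box_min` and `box_max`, rounded to integers and deduplicated (so the
#' returned count can be smaller than `n_boxes`).  Endpoints are always
#' included.
#'
#' @param box_min,box_max Smallest and largest box size in samples
#'   (defaults 4 and 251).
#' @param n_boxes Nominal number of sizes (default 40).
#' @return Strictly increasing integer vector.
#' @examples
#' range(make_box_sizes())
#' @export
make_box_sizes <- function(box_min = 4, box_max = 251, n_boxes = 40) {
  if (box_min < 4 || box_min >= box_max || n_boxes < 2) {
    abort("Need 4 <= box_min < box_max and n_boxes >= 2.",
          class = "emg_parameter_error")
  }
  sizes <- round(exp(seq(log(box_min), log(box_max), length.out = n_boxes)))
  sort(unique(as.integer(sizes)))
}

#' Detrended fluctuation analysis
#'
#' Estimates the scaling exponent `alpha` of a series: the profile
#' (cumulative sum of the mean-subtracted series) is split into
#' non-overlapping boxes of equal size anchored at the series start
#' (remainder samples discarded), a least-squares line is removed within
#' each box, and the fluctuation `F(n)` is the root-mean-square of the
#' residuals over all retained samples.  `alpha` is the ordinary
#' least-squares slope of `log10 F(n)` against `log10 n` across box sizes.
#'
#' Interpretation: `alpha = 0.5` for white noise, `1` for pink (1/f)
#' noise, `1.5` for brown (integrated white) noise; `alpha < 0.5`
#' indicates anti-correlated samples, and `0.5 < alpha < 1` long-range
#' power-law correlations.
#'
#' @param x Numeric series, not constant, with `length(x) >= 4 * box_min`.
#' @param box_min,box_max,n_boxes Box-size grid, see [make_box_sizes()].
#'   Sizes above `length(x) / 2` are dropped with a warning.
#' @return An object of class `dfa_result`: list with `box_sizes`,
#'   `fluctuations`, `alpha`, `intercept` and `fit_r2`.
#' @examples
#' x <- gen_colored_noise(2048, beta = 0, seed = 7)
#' dfa(x, box_max = 512)$alpha
#' @export
dfa <- function(x, box_min = 4, box_max = 251, n_boxes = 40) {
  n <- length(x)
  if (n < 4 * box_min) {
    abort("Series too short for DFA at this `box_min`.",
          class = "emg_parameter_error")
  }
  if (sd(x) == 0) {
    abort("Constant series: all detrended fluctuations are zero.",
          class = "emg_degenerate_input")
  }
  sizes <- make_box_sizes(box_min, box_max, n_boxes)
  if (max(sizes) > n / 2) {
    warn("Box sizes above length/2 dropped.", class = "emg_truncated_scales")
    sizes <- sizes[sizes <= n / 2]
    if (length(sizes) < 2) {
      abort("Fewer than two usable box sizes.", class = "emg_parameter_error")
    }
  }
  z <- cumsum(x - mean(x))
  fluct <- vapply(sizes, function(bs) {
    nb <- n %/% bs
    zz <- matrix(z[seq_len(nb * bs)], nrow = bs)
    t <- seq_len(bs)
    st <- sum(t); stt <- sum(t^2)
    sz <- colSums(zz)
    stz <- as.numeric(crossprod(t, zz))
    denom <- bs * stt - st^2
    slope <- (bs * stz - st * sz) / denom
    inter <- (sz - slope * st) / bs
    res <- zz - outer(t, slope) - matrix(inter, bs, nb, byrow = TRUE)
    sqrt(mean(res^2))
  }, numeric(1))
  keep <- fluct > 0
  if (!all(keep)) {
    warn("Scales with zero fluctuation dropped.", class = "emg_truncated_scales")
    sizes <- sizes[keep]; fluct <- fluct[keep]
    if (length(sizes) < 2) {
      abort("Fewer than two usable box sizes.", class = "emg_degenerate_input")
    }
  }
  fit <- lm(log10(fluct) ~ log10(sizes))
  structure(list(box_sizes = sizes, fluctuations = fluct,
                 alpha = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 fit_r2 = summary(fit)$r.squared),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("DFA: alpha = %.4f over %d box sizes [%d, %d] (R^2 = %.4f)\n",
              x$alpha, length(x$box_sizes), min(x$box_sizes),
              max(x$box_sizes), x$fit_r2))
  invisible(x)
}

#' @method tidy dfa_result
#' @export
tidy.dfa_result <- function(x, ...) {
  tibble::tibble(box_size = x$box_sizes, fluctuation = x$fluctuations)
}

#' @method glance dfa_result
#' @export
glance.dfa_result <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, intercept = x$intercept,
                 fit_r2 = x$fit_r2, n_scales = length(x$box_sizes))
}

#' @method autoplot dfa_result
#' @export
autoplot.dfa_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$box_size, y = .data$fluctuation)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$alpha, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "box size n (samples)", y = "F(n)",
                  title = sprintf("DFA scaling: alpha = %.3f", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Export a DFA fluctuation curve as two-column text
#'
#' @param result A `dfa_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fluctuation_curve <- function(result, path) {
  readr::write_tsv(tidy(result), path)
  invisible(path)
}
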