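#' Sample entropy
#'
#' SampEn(m, r) is the negative natural logarithm of the conditional
#' probability that two sequences matching for `m` points (within tolerance
#' `r`, Chebyshev distance, self-matches excluded) also match at the next
#' point: `SampEn = -ln(A / B)`, where `B` counts template pairs of length
#' `m` within `r` and `A` those of length `m + 1`.  Higher values indicate
#' a less regular, more complex signal.
#'
#' Both counts run over the same `N - m * delay` templates, so the ratio is
#' a proper conditional probability.  The tolerance is `r_fraction` times
#' the sample SD of `x`, making the measure invariant to scaling and
#' offset of the signal.
#'
#' @param x Numeric series of length at least `m + 2`.
#' @param m Embedding length (default 2).
#' @param r_fraction Tolerance as a multiple of `sd(x)` (default 0.2).
#' @param delay Embedding delay in samples (default 1).
#' @return An object of class `sampen_result`: a list with `value` (nats),
#'   `match_prob_a`, `match_prob_b`, `n_templates` and `flag`
#'   (`"ok"` or `"no_matches"` when no template pair matches at length
#'   `m + 1`, in which case `value` is `+Inf`).
#' @examples
#' x <- gen_colored_noise(500, beta = 0, seed = 1)
#' sample_entropy(x)$value
#' @export
sample_entropy <- function(x, m = 2, r_fraction = 0.2, delay = 1) {
  n <- length(x)
  if (m < 1 || r_fraction <= 0 || delay < 1) {
    abort("Need m >= 1, r_fraction > 0, delay >= 1.", class = "emg_parameter_error")
  }
  if (n < m * delay + 2) {
    abort("Series too short for the requested embedding.",
          class = "emg_parameter_error")
  }
  s <- sd(x)
  if (s == 0) {
    abort("Constant series: tolerance r would be zero.",
          class = "emg_degenerate_input")
  }
  r <- r_fraction * s
  nt <- n - m * delay  # templates for both lengths m and m + 1
  # Chebyshev distance matrices built component-wise; D_m for length-m
  # templates, extended by one more component for length m + 1.
  idx <- seq_len(nt)
  dmat <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    comp <- x[idx + k * delay]
    dmat <- pmax(dmat, abs(outer(comp, comp, "-")))
  }
  upper <- upper.tri(dmat)
  b_count <- sum(dmat[upper] <= r)
  comp <- x[idx + m * delay]
  dmat <- pmax(dmat, abs(outer(comp, comp, "-")))
  a_count <- sum(dmat[upper] <= r)
  pairs <- nt * (nt - 1) / 2
  match_b <- b_count / pairs
  match_a <- a_count / pairs
  flag <- "ok"
  if (a_count == 0 || b_count == 0) {
    flag <- "no_matches"
    value <- Inf
  } else {
    value <- -log(a_count / b_count)
  }
  structure(list(value = value, match_prob_a = match_a,
                 match_prob_b = match_b, n_templates = nt, flag = flag),
            class = "sampen_result")
}

#' @export
print.sampen_result <- function(x, ...) {
  cat(sprintf("SampEn = %.4f nats  (B = %.4g, A = %.4g, %d templates%s)\n",
              x$value, x$match_prob_b, x$match_prob_a, x$n_templates,
              if (x$flag != "ok") paste0(", ", x$flag) else ""))
  invisible(x)
}

#' @method tidy sampen_result
#' @export
tidy.sampen_result <- function(x, ...) {
  tibble::tibble(value = x$value, match_prob_a = x$match_prob_a,
                 match_prob_b = x$match_prob_b, n_templates = x$n_templates,
                 flag = x$flag)
}
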