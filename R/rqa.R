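#' Time-delay embedding
#'
#' Builds the delayed-coordinate vectors
#' `y_i = (x_i, x_{i+tau}, ..., x_{i+(d-1)tau})` used for recurrence
#' analysis.
#'
#' @param x Numeric series with `length(x) > (dim - 1) * delay`.
#' @param dim Embedding dimension `d` (default 10).
#' @param delay Time delay `tau` in samples (default 5).
#' @return A numeric matrix with `length(x) - (dim - 1) * delay` rows and
#'   `dim` columns.
#' @examples
#' embed_delay(1:10, dim = 3, delay = 2)
#' @export
embed_delay <- function(x, dim = 10, delay = 5) {
  if (dim < 1 || delay < 1) {
    abort("Need dim >= 1 and delay >= 1.", class = "emg_parameter_error")
  }
  n <- length(x)
  nv <- n - (dim - 1) * delay
  if (nv < 1) {
    abort("Series too short for the requested embedding.",
          class = "emg_parameter_error")
  }
  out <- matrix(0, nv, dim)
  for (k in seq_len(dim)) out[, k] <- x[(1 + (k - 1) * delay):((k - 1) * delay + nv)]
  out
}

#' Recurrence matrix of embedded vectors
#'
#' Pairwise Euclidean distances are normalized by the maximum pairwise
#' distance; a recurrence is scored when the normalized distance is
#' strictly smaller than `radius_fraction`.  When every pairwise distance
#' is zero (a constant signal) normalization is degenerate: all points are
#' marked recurrent and the result is flagged.
#'
#' @param vectors Matrix of embedded vectors (rows), e.g. from
#'   [embed_delay()].
#' @param radius_fraction Threshold radius as a fraction of the maximum
#'   distance (default 0.25).
#' @return A logical matrix with attributes `degenerate` (logical).
#' @export
recurrence_matrix <- function(vectors, radius_fraction = 0.25) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2) {
    abort("Need at least 2 embedded vectors.", class = "emg_parameter_error")
  }
  if (radius_fraction <= 0 || radius_fraction > 1) {
    abort("`radius_fraction` must lie in (0, 1].", class = "emg_parameter_error")
  }
  d <- as.matrix(stats::dist(vectors))
  dmax <- max(d)
  if (dmax == 0) {
    rec <- matrix(TRUE, nrow(d), ncol(d))
    attr(rec, "degenerate") <- TRUE
    return(rec)
  }
  rec <- d / dmax < radius_fraction
  attr(rec, "degenerate") <- FALSE
  rec
}

#' Recurrence quantification measures
#'
#' Computes the percentage of recurrence (%Rec, density of recurrent point
#' pairs) and the percentage of determinism (%Det, share of recurrent
#' points lying on diagonal segments of length at least `l_min`) from a
#' recurrence matrix.  Diagonals within `theiler` of the line of identity
#' are excluded from every count (`theiler = 1` excludes only the line of
#' identity itself).
#'
#' @param rec Logical recurrence matrix from [recurrence_matrix()].
#' @param l_min Minimum diagonal length counted as deterministic
#'   (default 3).
#' @param theiler Half-width of the excluded band around the line of
#'   identity (default 1).
#' @return An object of class `rqa_result`: list with `pct_rec`, `pct_det`
#'   (both in percent), `n_vectors`, `diagonal_hist` (tibble of diagonal
#'   segment lengths and counts, both triangles) and `degenerate`.
#' @export
rqa_measures <- function(rec, l_min = 3, theiler = 1) {
  if (l_min < 2) abort("`l_min` must be >= 2.", class = "emg_parameter_error")
  n <- nrow(rec)
  degenerate <- isTRUE(attr(rec, "degenerate"))
  if (degenerate) {
    # identical vectors: every point recurs and every diagonal is unbroken
    return(structure(list(pct_rec = 100, pct_det = 100, n_vectors = n,
                          diagonal_hist = tibble::tibble(
                            length = seq.int(n - theiler, 1L),
                            count = rep(2L, n - theiler)),
                          degenerate = TRUE, l_min = l_min, theiler = theiler),
                     class = "rqa_result"))
  }
  offs <- seq.int(theiler, n - 1L)
  total_pts <- 0
  rec_pts <- 0
  det_pts <- 0
  lens_list <- vector("list", length(offs))
  for (k in offs) {
    diag_vec <- rec[cbind(seq_len(n - k), seq_len(n - k) + k)]
    total_pts <- total_pts + length(diag_vec)
    nrec <- sum(diag_vec)
    if (nrec == 0) next
    rec_pts <- rec_pts + nrec
    r <- rle(diag_vec)
    seg <- r$lengths[r$values]
    det_pts <- det_pts + sum(seg[seg >= l_min])
    lens_list[[k - theiler + 1L]] <- seg
  }
  lens <- unlist(lens_list)
  # upper triangle scanned; symmetric lower triangle contributes the same
  pct_rec <- if (total_pts > 0) 100 * rec_pts / total_pts else 0
  pct_det <- if (rec_pts > 0) 100 * det_pts / rec_pts else 0
  hist <- if (length(lens) > 0) {
    tb <- table(lens)
    tibble::tibble(length = as.integer(names(tb)),
                   count = 2L * as.integer(tb))
  } else {
    tibble::tibble(length = integer(0), count = integer(0))
  }
  structure(list(pct_rec = pct_rec, pct_det = pct_det, n_vectors = n,
                 diagonal_hist = hist, degenerate = degenerate,
                 l_min = l_min, theiler = theiler),
            class = "rqa_result")
}

#' Recurrence quantification analysis of a series
#'
#' Convenience wrapper: embed with [embed_delay()], threshold with
#' [recurrence_matrix()], quantify with [rqa_measures()].
#'
#' @inheritParams embed_delay
#' @inheritParams recurrence_matrix
#' @inheritParams rqa_measures
#' @param keep_matrix Keep the recurrence matrix in the result (for
#'   plotting; default `FALSE`).
#' @return An `rqa_result` (see [rqa_measures()]); with
#'   `keep_matrix = TRUE` it also carries the logical matrix as `$matrix`.
#' @examples
#' x <- sin(2 * pi * (1:400) / 25)
#' rqa(x, dim = 3, delay = 6)$pct_det
#' @export
rqa <- function(x, dim = 10, delay = 5, radius_fraction = 0.25, l_min = 3,
                theiler = 1, keep_matrix = FALSE) {
  vec <- embed_delay(x, dim = dim, delay = delay)
  rec <- recurrence_matrix(vec, radius_fraction = radius_fraction)
  res <- rqa_measures(rec, l_min = l_min, theiler = theiler)
  if (keep_matrix) res$matrix <- rec
  res
}

#' @export
print.rqa_result <- function(x, ...) {
  cat(sprintf("RQA: %%Rec = %.2f, %%Det = %.2f (%d vectors%s)\n",
              x$pct_rec, x$pct_det, x$n_vectors,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @method tidy rqa_result
#' @export
tidy.rqa_result <- function(x, ...) {
  tibble::tibble(pct_rec = x$pct_rec, pct_det = x$pct_det,
                 n_vectors = x$n_vectors, degenerate = x$degenerate)
}

#' @method autoplot rqa_result
#' @export
autoplot.rqa_result <- function(object, ...) {
  if (is.null(object$matrix)) {
    abort("Recompute with `rqa(..., keep_matrix = TRUE)` to plot.",
          class = "emg_parameter_error")
  }
  df <- which(object$matrix, arr.ind = TRUE)
  df <- tibble::tibble(i = df[, 1], j = df[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_point(shape = 15, size = 0.3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "vector index i", y = "vector index j",
                  title = sprintf("Recurrence plot (%%Rec %.1f, %%Det %.1f)",
                                  object$pct_rec, object$pct_det)) +
    ggplot2::theme_minimal()
}

#' Export a recurrence plot as a dense 0/1 text matrix
#'
#' @param result An `rqa_result` computed with `keep_matrix = TRUE`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recurrence_matrix <- function(result, path) {
  if (is.null(result$matrix)) {
    abort("Recompute with `rqa(..., keep_matrix = TRUE)` to export.",
          class = "emg_parameter_error")
  }
  utils::write.table(1L * result$matrix, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Estimate the embedding delay by average mutual information
#'
#' Histogram estimator of the average mutual information (AMI) between
#' `x_t` and `x_{t+lag}`; the suggested delay is the first local minimum of
#' the AMI curve.  The number of histogram bins follows Sturges' rule
#' (`ceiling(log2(n)) + 1`) unless overridden.  If no local minimum occurs
#' within `max_lag`, `max_lag` is returned with a warning.
#'
#' @param x Numeric series.
#' @param max_lag Largest lag examined (default 50).
#' @param n_bins Number of histogram bins (default: Sturges' rule).
#' @return A list with `delay` and the `ami` curve (tibble lag, ami).
#' @export
estimate_delay_ami <- function(x, max_lag = 50, n_bins = NULL) {
  n <- length(x)
  if (n <= 4 * max_lag) {
    abort("Series too short for the requested `max_lag`.",
          class = "emg_parameter_error")
  }
  if (is.null(n_bins)) n_bins <- ceiling(log2(n)) + 1
  br <- seq(min(x), max(x), length.out = n_bins + 1)
  ix <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  ami_at <- function(lag) {
    a <- factor(ix[1:(n - lag)], levels = seq_len(n_bins))
    b <- factor(ix[(1 + lag):n], levels = seq_len(n_bins))
    tab <- table(a, b) / (n - lag)
    pa <- rowSums(tab); pb <- colSums(tab)
    m <- tab * log(tab / outer(pa, pb))
    sum(m[tab > 0])
  }
  ami <- vapply(seq_len(max_lag), ami_at, numeric(1))
  # first lag that is a local minimum; lag 0 has maximal AMI by definition
  prev <- c(Inf, ami[-max_lag])
  nxt <- c(ami[-1], Inf)
  cand <- which(ami < nxt & ami <= prev)
  if (length(cand) == 0) {
    warn("No AMI local minimum found; returning `max_lag`.",
         class = "emg_no_minimum")
    delay <- max_lag
  } else {
    delay <- cand[1]
  }
  list(delay = delay,
       ami = tibble::tibble(lag = seq_len(max_lag), ami = ami))
}

#' Estimate the embedding dimension by false nearest neighbors
#'
#' Kennel-style criterion: for each dimension `d`, the nearest neighbor of
#' every embedded point is found in `d` dimensions and flagged as false if
#' the extra coordinate at `d + 1` inflates the distance beyond `r_tol`
#' times the `d`-dimensional distance, or beyond `a_tol` times the series
#' SD.  The estimate is the smallest `d` whose false-neighbor fraction
#' drops below `threshold`; if none qualifies, `max_dim` is returned with
#' a warning.
#'
#' @param x Numeric series.
#' @param delay Embedding delay.
#' @param max_dim Largest dimension examined (default 12).
#' @param r_tol,a_tol Kennel tolerances (defaults 10 and 2).
#' @param threshold Acceptable false-neighbor fraction (default 0.01).
#' @return A list with `dim` and the `fnn` curve (tibble dim, fraction).
#' @export
estimate_dimension_fnn <- function(x, delay = 5, max_dim = 12, r_tol = 10,
                                   a_tol = 2, threshold = 0.01) {
  n <- length(x)
  if (n <= (max_dim + 1) * delay + 10) {
    abort("Series too short for the requested `max_dim`.",
          class = "emg_parameter_error")
  }
  sx <- sd(x)
  frac <- numeric(max_dim)
  chosen <- NA_integer_
  for (d in seq_len(max_dim)) {
    v <- embed_delay(x, dim = d, delay = delay)
    nv <- n - d * delay  # points whose (d+1)-th coordinate exists
    v <- v[seq_len(nv), , drop = FALSE]
    dm <- as.matrix(stats::dist(v))
    diag(dm) <- Inf
    nn <- apply(dm, 1, which.min)
    rd <- dm[cbind(seq_len(nv), nn)]
    extra <- abs(x[seq_len(nv) + d * delay] - x[nn + d * delay])
    rd1 <- sqrt(rd^2 + extra^2)
    # floor the denominator: exactly recurring states (distance ~ 0 up to
    # floating-point noise) must not be flagged by the ratio criterion
    floor_d <- sqrt(.Machine$double.eps) * sx
    false_nb <- (extra / pmax(rd, floor_d) > r_tol) | (rd1 / sx > a_tol)
    frac[d] <- mean(false_nb)
    if (is.na(chosen) && frac[d] < threshold) {
      chosen <- d
      frac <- frac[seq_len(d)]
      break
    }
  }
  if (is.na(chosen)) {
    warn("False-neighbor fraction never fell below threshold; returning `max_dim`.",
         class = "emg_no_minimum")
    chosen <- max_dim
  }
  list(dim = chosen,
       fnn = tibble::tibble(dim = seq_along(frac), fraction = frac))
}
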