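#' Generate colored noise by spectral synthesis
#'
#' Synthesizes a zero-mean Gaussian-type series whose power spectrum follows
#' `S(f) ~ f^(-beta)`: `beta = 0` gives white noise, `beta = 1` pink (1/f)
#' noise and `beta = 2` brown (integrated white) noise.  Under detrended
#' fluctuation analysis such series have an expected scaling exponent
#' `alpha = (beta + 1) / 2`, i.e. 0.5, 1.0 and 1.5 respectively, which makes
#' them the canonical calibration inputs for [dfa()].
#'
#' The synthesis works in the frequency domain: Fourier amplitudes are set
#' proportional to `f^(-beta/2)`, phases are drawn uniformly at random, and
#' the inverse transform (with Hermitian symmetry enforced) yields a real
#' series with exactly the target spectral shape.  This gives direct control
#' of the exponent, unlike autoregressive approximations.
#'
#' @param n Length of the series in samples (at least 16).
#' @param beta Spectral exponent in `[-2, 4]`.
#' @param seed Optional integer seed.  When supplied the global RNG state is
#'   untouched and the output is reproducible bit-for-bit.
#' @param band Optional length-2 frequency band (as fractions of the
#'   sampling rate, each in `(0, 0.5]`); amplitudes outside the band are set
#'   to zero, producing band-limited colored noise.  Used by the EMG
#'   surrogate generator.
#' @return A zero-mean numeric vector of length `n`.
#' @examples
#' x <- gen_colored_noise(1024, beta = 1, seed = 42)
#' mean(x)
#' @export
gen_colored_noise <- function(n, beta = 0, seed = NULL, band = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 16) {
    abort("`n` must be a single number >= 16.", class = "emg_invalid_spec")
  }
  if (!is.numeric(beta) || length(beta) != 1 || beta < -2 || beta > 4) {
    abort("`beta` must be a single number in [-2, 4].", class = "emg_invalid_spec")
  }
  if (!is.null(band)) {
    if (length(band) != 2 || any(band <= 0) || any(band > 0.5) || band[1] >= band[2]) {
      abort("`band` must be increasing fractions of the sampling rate in (0, 0.5].",
            class = "emg_invalid_spec")
    }
  }
  n <- as.integer(n)
  synth <- function() {
    nf <- n %/% 2L
    f <- seq_len(nf) / n
    amp <- f^(-beta / 2)
    if (!is.null(band)) amp[f < band[1] | f > band[2]] <- 0
    ph <- runif(nf, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = ph)
    full <- complex(real = numeric(n))
    full[2:(nf + 1L)] <- spec
    if (n %% 2L == 0L) {
      # Nyquist bin must be real for a real-valued series
      full[nf + 1L] <- complex(real = amp[nf] * cos(ph[nf]))
      if (nf > 1L) full[(nf + 2L):n] <- Conj(spec[(nf - 1L):1L])
    } else {
      full[(nf + 2L):n] <- Conj(spec[nf:1L])
    }
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    x - mean(x)
  }
  if (is.null(seed)) synth() else withr::with_seed(seed, synth())
}
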