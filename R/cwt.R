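# Analytic Morlet continuous wavelet transform (FFT implementation).

#' CWT configuration
#'
#' @param omega0 Morlet centre frequency in rad (default 6, the standard
#'   analytic-Morlet centre giving ~6 oscillations under the envelope).
#' @param voices_per_octave Scales per octave (default 12).
#' @param fmin,fmax Frequency range of the scalogram in Hz (defaults 2-60,
#'   covering delta through low gamma).
#' @return An object of class `cwt_config`.
#' @export
cwt_config <- function(omega0 = 6, voices_per_octave = 12L, fmin = 2, fmax = 60) {
  assert_scalar_pos(omega0, "omega0")
  assert_count(voices_per_octave, "voices_per_octave")
  assert_scalar_pos(fmin, "fmin")
  if (fmax <= fmin) stop("`fmax` must exceed `fmin`", call. = FALSE)
  structure(list(omega0 = omega0, voices_per_octave = as.integer(voices_per_octave),
                 fmin = fmin, fmax = fmax),
            class = "cwt_config")
}

# geometric frequency grid at v voices per octave over [fmin, fmax]
cwt_freqs <- function(cfg) {
  n_oct <- log2(cfg$fmax / cfg$fmin)
  j <- 0:floor(n_oct * cfg$voices_per_octave + 1e-9)
  cfg$fmin * 2^(j / cfg$voices_per_octave)
}

#' Analytic Morlet scalogram of a single channel
#'
#' Correlates the signal with scaled analytic Morlet wavelets over a
#' log-spaced frequency grid (`voices_per_octave` scales per octave covering
#' `[fmin, fmax]`). The wavelet spectrum is a Gaussian
#' `exp(-(s*w - omega0)^2 / 2)` supported on positive frequencies only, so the
#' transform is one-sided (analytic). Each scale's frequency response is
#' unit-peak normalised so magnitudes are comparable across rows. Pixel values
#' are the coefficient magnitudes `|W(a, b)|`.
#'
#' @param x Single-channel numeric signal (finite values).
#' @param fs Sampling rate in Hz.
#' @param cfg A [cwt_config()]; `fmax` above Nyquist is clipped with a warning.
#' @param channel_label,subject_id,epoch_index Metadata attached to the image.
#' @return A [tf_image()] with `repr = "CWT"`, rows ordered by ascending
#'   frequency.
#' @export
cwt_scalogram <- function(x, fs, cfg = cwt_config(),
                          channel_label = NA_character_,
                          subject_id = NA_character_, epoch_index = NA_integer_) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`x` must be a finite numeric signal", call. = FALSE)
  assert_scalar_pos(fs, "fs")
  if (cfg$fmax > fs / 2) {
    warning(sprintf("fmax (%g Hz) above Nyquist; clipped to %g Hz", cfg$fmax, fs / 2))
    cfg$fmax <- fs / 2
  }
  n <- length(x)
  freqs <- cwt_freqs(cfg)
  xf <- stats::fft(x)
  w <- 2 * pi * (0:(n - 1L)) / n            # digital angular frequency grid
  pos <- w > 0 & w <= pi                    # analytic: positive frequencies only
  vals <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    s <- cfg$omega0 / (2 * pi * freqs[i] / fs)   # scale in samples
    psi <- rep(0, n)
    psi[pos] <- exp(-0.5 * (s * w[pos] - cfg$omega0)^2)
    vals[i, ] <- Mod(stats::fft(xf * psi, inverse = TRUE) / n)
  }
  tf_image(vals, time_axis = (0:(n - 1L)) / fs, freq_axis = freqs,
           repr = "CWT", channel_label = channel_label,
           subject_id = subject_id, epoch_index = epoch_index)
}
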