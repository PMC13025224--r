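# Synthetic EEG cohorts and analytic test tones with known ground truth.
#
# The generator emulates resting-state EEG as a 1/f^beta background plus
# band-limited oscillations (delta..gamma), optional mains interference and
# white sensor noise. A binary class effect (responder vs non-responder) is
# injected as a multiplicative band-power difference restricted to a set of
# effect channels, which makes the effect recoverable by band-power analysis,
# by time-frequency imaging and by the downstream classifier, with known
# spatial ground truth.

#' Canonical EEG frequency bands (Hz)
#'
#' @return Named list of `c(lo, hi)` band edges in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 45))
}

#' Specification of a synthetic EEG cohort
#'
#' @param n_responders,n_nonresponders Numbers of subjects per class.
#' @param n_channels Number of channels (default 19; labelled with the 10-20
#'   montage when 19).
#' @param duration_s Recording length in seconds (default 300, i.e. the
#'   five-minute resting-state recordings the pipeline expects).
#' @param fs Sampling rate in Hz.
#' @param band_powers Named list with elements `R` and `NR`, each a named
#'   numeric vector of relative band amplitudes over [eeg_bands()]. The class
#'   difference between the two profiles is applied only at `effect_channels`;
#'   all other channels use the mean of the two profiles. The default doubles
#'   alpha power for responders.
#' @param effect_channels Channel labels carrying the class difference
#'   (default `c("O1", "O2")`, i.e. an occipital alpha effect).
#' @param line_freq Mains frequency in Hz (default 50). Set `line_amp = 0` to
#'   disable the interference component.
#' @param line_amp Mains interference amplitude in uV.
#' @param noise_sd Additive white noise standard deviation in uV.
#' @param subject_sd Log-normal standard deviation of the per-subject global
#'   amplitude jitter (physiological between-subject variability).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_responders, n_nonresponders,
                        n_channels = 19L, duration_s = 300, fs = 256,
                        band_powers = NULL,
                        effect_channels = c("O1", "O2"),
                        line_freq = 50, line_amp = 1, noise_sd = 2,
                        subject_sd = 0.05, seed = 1L) {
  assert_count(n_responders, "n_responders", min = 0L)
  assert_count(n_nonresponders, "n_nonresponders", min = 0L)
  assert_count(n_channels, "n_channels", min = 1L)
  assert_scalar_pos(duration_s, "duration_s")
  assert_scalar_pos(fs, "fs")
  if (is.null(band_powers)) {
    base <- c(delta = 1.5, theta = 1.0, alpha = 1.0, beta = 0.6, gamma = 0.3)
    band_powers <- list(R = replace(base, "alpha", 2.0), NR = base)
  }
  if (!all(c("R", "NR") %in% names(band_powers)))
    stop("`band_powers` must have elements 'R' and 'NR'", call. = FALSE)
  labels <- if (n_channels == 19L) montage_1020() else paste0("Ch", seq_len(n_channels))
  if (!all(effect_channels %in% labels))
    stop("`effect_channels` must be a subset of the channel labels", call. = FALSE)
  structure(list(
    n_responders = as.integer(n_responders),
    n_nonresponders = as.integer(n_nonresponders),
    n_channels = as.integer(n_channels), duration_s = duration_s, fs = fs,
    band_powers = band_powers, effect_channels = effect_channels,
    channel_labels = labels,
    line_freq = line_freq, line_amp = line_amp, noise_sd = noise_sd,
    subject_sd = subject_sd, seed = as.integer(seed)),
    class = "cohort_spec")
}

# band-limited Gaussian noise via FFT masking with raised-cosine edges
band_noise <- function(n, fs, lo, hi, edge = 0.5) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)                       # two-sided frequency magnitude
  w <- rep(0, n)
  inside <- f >= lo & f <= hi
  w[inside] <- 1
  ramp_lo <- f >= lo - edge & f < lo
  w[ramp_lo] <- 0.5 * (1 + cos(pi * (lo - f[ramp_lo]) / edge))
  ramp_hi <- f > hi & f <= hi + edge
  w[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - hi) / edge))
  y <- Re(stats::fft(xf * w, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

# 1/f^beta background (amplitude-shaped white noise)
pink_noise <- function(n, beta = 1) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- seq(0, 1, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, 1 - f)
  amp <- c(0, 1 / f[-1]^(beta / 2))
  y <- Re(stats::fft(xf * amp, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate a labelled synthetic EEG cohort
#'
#' Draws `n_responders + n_nonresponders` multichannel recordings according to
#' the spec. Responders are listed first. Each channel is a 1/f background
#' plus band-limited oscillations whose relative amplitudes follow the class
#' profile at the effect channels and the pooled profile elsewhere, plus
#' mains interference and white noise, scaled to microvolt magnitudes.
#'
#' @param spec A [cohort_spec()].
#' @return List of `eeg_recording` objects with `label` `"R"` or `"NR"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- round(spec$duration_s * spec$fs)
  t <- (seq_len(n) - 1L) / spec$fs
  bands <- eeg_bands()
  pooled <- (spec$band_powers$R + spec$band_powers$NR) / 2
  labs <- c(rep("R", spec$n_responders), rep("NR", spec$n_nonresponders))
  out <- vector("list", length(labs))
  for (s in seq_along(labs)) {
    cls <- labs[s]
    gain <- exp(stats::rnorm(1L, 0, spec$subject_sd))
    X <- matrix(0, spec$n_channels, n)
    for (ch in seq_len(spec$n_channels)) {
      is_eff <- spec$channel_labels[ch] %in% spec$effect_channels
      prof <- if (is_eff) spec$band_powers[[cls]] else pooled
      sig <- 4 * pink_noise(n)
      for (b in names(bands)) {
        # profiles are relative band *powers*; oscillation amplitude is sqrt
        amp <- sqrt(prof[[b]])
        if (is.na(amp) || amp <= 0) next
        hi <- min(bands[[b]][2L], 0.45 * spec$fs)
        if (hi <= bands[[b]][1L]) next
        sig <- sig + 3 * amp * band_noise(n, spec$fs, bands[[b]][1L], hi)
      }
      if (spec$line_amp > 0 && spec$line_freq < spec$fs / 2) {
        phi <- stats::runif(1L, 0, 2 * pi)
        sig <- sig + spec$line_amp * sin(2 * pi * spec$line_freq * t + phi)
      }
      sig <- gain * sig + stats::rnorm(n, 0, spec$noise_sd)
      X[ch, ] <- sig
    }
    out[[s]] <- eeg_recording(
      samples = X, fs = spec$fs, channel_labels = spec$channel_labels,
      subject_id = sprintf("S%02d", s), label = cls, therapy = "synthetic")
  }
  out
}

#' Specification of a multi-tone calibration signal
#'
#' @param frequencies Tone frequencies in Hz (all strictly below `fs / 2`).
#' @param amplitudes Tone amplitudes (recycled to the number of tones).
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param noise_sd Additive white-noise standard deviation.
#' @return An object of class `tone_spec`.
#' @export
tone_spec <- function(frequencies, amplitudes = 1, duration_s = 15, fs = 512,
                      noise_sd = 0) {
  assert_scalar_pos(duration_s, "duration_s")
  assert_scalar_pos(fs, "fs")
  if (any(frequencies >= fs / 2))
    stop("all `frequencies` must be below the Nyquist rate fs/2", call. = FALSE)
  structure(list(frequencies = frequencies,
                 amplitudes = rep_len(amplitudes, length(frequencies)),
                 duration_s = duration_s, fs = fs, noise_sd = noise_sd),
            class = "tone_spec")
}

#' Generate a single-channel multi-tone signal
#'
#' Sum of sinusoids plus white noise; the exact ground-truth frequency list is
#' attached as an attribute so downstream decompositions can be validated.
#'
#' @param spec A [tone_spec()].
#' @return Numeric vector with attributes `fs` and `frequencies`.
#' @export
generate_tones <- function(spec) {
  stopifnot(inherits(spec, "tone_spec"))
  n <- round(spec$duration_s * spec$fs)
  t <- (seq_len(n) - 1L) / spec$fs
  x <- rep(0, n)
  for (i in seq_along(spec$frequencies))
    x <- x + spec$amplitudes[i] * cos(2 * pi * spec$frequencies[i] * t)
  if (spec$noise_sd > 0) x <- x + stats::rnorm(n, 0, spec$noise_sd)
  structure(x, fs = spec$fs, frequencies = spec$frequencies)
}
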