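# Short-time Fourier transform and the aggregate VMD spectrogram.

#' STFT configuration
#'
#' @param win_len Hamming window length in samples (default 256).
#' @param overlap Overlap between consecutive windows in samples (default 250,
#'   i.e. a hop of 6 samples for dense temporal sampling).
#' @param nfft FFT length, zero-padded (default 7680).
#' @param fs Sampling rate in Hz (default 512).
#' @param fmax_display Upper frequency bound of the rendered spectrogram image
#'   in Hz (default 60).
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(win_len = 256L, overlap = 250L, nfft = 7680L,
                        fs = 512, fmax_display = 60) {
  assert_count(win_len, "win_len")
  assert_count(overlap, "overlap", min = 0L)
  assert_count(nfft, "nfft")
  if (overlap >= win_len) stop("`overlap` must be smaller than `win_len`", call. = FALSE)
  if (nfft < win_len) stop("`nfft` must be at least `win_len`", call. = FALSE)
  structure(list(win_len = as.integer(win_len), overlap = as.integer(overlap),
                 hop = as.integer(win_len - overlap), nfft = as.integer(nfft),
                 fs = fs, fmax_display = fmax_display),
            class = "stft_config")
}

#' Complex STFT of a single channel
#'
#' Hamming-windowed frames with hop `win_len - overlap`, zero-padded to
#' `nfft` points; one-sided output (frequencies 0 to Nyquist).
#'
#' @param x Numeric signal of length at least `win_len`.
#' @param cfg An [stft_config()].
#' @return Complex matrix (frequency bins x frames) with attributes `f`
#'   (Hz), `t` (frame-centre seconds) and `hop`.
#' @export
stft_spectrogram <- function(x, cfg = stft_config()) {
  n <- length(x)
  if (n < cfg$win_len)
    stop(sprintf("signal length %d shorter than window length %d", n, cfg$win_len),
         call. = FALSE)
  win <- as.numeric(signal::hamming(cfg$win_len))
  n_frames <- (n - cfg$win_len) %/% cfg$hop + 1L
  starts <- (0:(n_frames - 1L)) * cfg$hop
  F <- matrix(0, cfg$nfft, n_frames)
  for (j in seq_len(n_frames))
    F[seq_len(cfg$win_len), j] <- x[starts[j] + seq_len(cfg$win_len)] * win
  S <- stats::mvfft(F)
  nh <- cfg$nfft %/% 2L + 1L
  S <- S[seq_len(nh), , drop = FALSE]
  structure(S,
            f = (0:(nh - 1L)) * cfg$fs / cfg$nfft,
            t = (starts + (cfg$win_len - 1L) / 2) / cfg$fs,
            hop = cfg$hop)
}

#' Aggregate complex spectrogram of a VMD mode set
#'
#' Sums the complex STFTs of all modes (the order of summation and transform
#' is immaterial by linearity, which is verified in the test suite) and
#' renders the magnitude restricted to `[0, fmax_display]` Hz.
#'
#' @param modes Numeric matrix, K x time (e.g. `vmd_result$modes`), all modes
#'   the same length.
#' @param cfg An [stft_config()].
#' @param channel_label,subject_id,epoch_index Metadata attached to the image.
#' @return A [tf_image()] with `repr = "VMD"`.
#' @export
aggregate_vmd_spectrogram <- function(modes, cfg = stft_config(),
                                      channel_label = NA_character_,
                                      subject_id = NA_character_,
                                      epoch_index = NA_integer_) {
  modes <- as.matrix(modes)
  if (nrow(modes) < 1L) stop("`modes` must contain at least one mode", call. = FALSE)
  acc <- NULL
  for (k in seq_len(nrow(modes))) {
    Sk <- stft_spectrogram(modes[k, ], cfg)
    acc <- if (is.null(acc)) Sk else {
      a <- unclass(acc) + unclass(Sk)
      attributes(a) <- attributes(Sk)
      a
    }
  }
  f <- attr(acc, "f")
  keep <- f <= cfg$fmax_display
  tf_image(Mod(unclass(acc))[keep, , drop = FALSE],
           time_axis = attr(acc, "t"), freq_axis = f[keep],
           repr = "VMD", channel_label = channel_label,
           subject_id = subject_id, epoch_index = epoch_index)
}
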