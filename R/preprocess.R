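# Preprocessing: zero-phase filtering, re-referencing, epoching, resampling.

# RBJ-cookbook second-order IIR notch at f0 with quality factor Q
notch_coef <- function(f0, fs, Q = 35) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase band-pass and notch filtering
#'
#' Applies a 4th-order Butterworth band-pass (default 0.5-70 Hz) and a
#' second-order IIR notch (default 50 Hz, Q = 35), both forward-reverse
#' (`filtfilt`) so the group delay is zero and no phase distortion is
#' introduced. Each channel is filtered independently.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band-pass corner frequencies in Hz.
#' @param notch Notch centre frequency in Hz, or `NULL` to skip the notch.
#' @param notch_q Notch quality factor.
#' @return The filtered recording (same shape).
#' @export
bandpass_notch <- function(rec, low = 0.5, high = 70, notch = 50, notch_q = 35) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (high >= nyq)
    stop(sprintf("band-pass upper edge (%g Hz) must be below Nyquist (%g Hz)",
                 high, nyq), call. = FALSE)
  bp <- signal::butter(4, c(low, high) / nyq, type = "pass")
  nc <- if (!is.null(notch) && notch < nyq) notch_coef(notch, rec$fs, notch_q) else NULL
  X <- rec$samples
  for (ch in seq_len(nrow(X))) {
    y <- signal::filtfilt(bp, X[ch, ])
    if (!is.null(nc)) y <- signal::filtfilt(signal::Arma(b = nc$b, a = nc$a), y)
    X[ch, ] <- y
  }
  rec$samples <- X
  rec
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' that at each time point the channel mean is zero. The projection is
#' idempotent.
#'
#' @param rec An [eeg_recording()] with at least two channels.
#' @return The re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$samples) < 2L)
    stop("common average reference requires at least 2 channels", call. = FALSE)
  rec$samples <- sweep(rec$samples, 2L, colMeans(rec$samples))
  rec
}

#' Segment a recording into non-overlapping fixed-length epochs
#'
#' Cuts `floor(duration / win_s)` non-overlapping windows from the start of
#' the recording; any trailing remainder is discarded. Optionally rejects
#' epochs whose peak absolute amplitude exceeds a threshold (a simple
#' amplitude-based stand-in for artifact rejection, off by default).
#'
#' @param rec An [eeg_recording()].
#' @param win_s Window length in seconds (default 15).
#' @param reject_amplitude_uv Peak-amplitude rejection threshold in microvolts,
#'   or `NULL` (default) to keep every epoch.
#' @return List of [eeg_epoch()] objects, with attribute `n_rejected`.
#' @export
segment_epochs <- function(rec, win_s = 15, reject_amplitude_uv = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_scalar_pos(win_s, "win_s")
  wlen <- round(win_s * rec$fs)
  n_ep <- floor(ncol(rec$samples) / wlen)
  if (n_ep < 1L) {
    warning("recording shorter than one window; returning no epochs")
    return(structure(list(), n_rejected = 0L))
  }
  eps <- vector("list", n_ep)
  for (i in seq_len(n_ep)) {
    idx <- ((i - 1L) * wlen + 1L):(i * wlen)
    eps[[i]] <- eeg_epoch(rec$samples[, idx, drop = FALSE], rec$fs,
                          rec$channel_labels, epoch_index = i,
                          subject_id = rec$subject_id, label = rec$label)
  }
  n_rej <- 0L
  if (!is.null(reject_amplitude_uv)) {
    keep <- vapply(eps, function(e) max(abs(e$samples)) <= reject_amplitude_uv,
                   logical(1L))
    n_rej <- sum(!keep)
    eps <- eps[keep]
  }
  structure(eps, n_rejected = n_rej)
}

#' Polyphase resampling of a recording to a target rate
#'
#' Resamples every channel with a polyphase anti-aliasing filter so that
#' recordings acquired at different rates share a common rate before
#' time-frequency imaging (512 Hz by default).
#'
#' @param rec An [eeg_recording()].
#' @param fs_target Target sampling rate in Hz.
#' @return The resampled recording.
#' @export
resample_recording <- function(rec, fs_target = 512) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (fs_target == rec$fs) return(rec)
  g <- gcd_int(round(fs_target), round(rec$fs))
  p <- round(fs_target) / g
  q <- round(rec$fs) / g
  Y <- t(apply(rec$samples, 1L, function(x) signal::resample(x, p, q)))
  rec$samples <- Y
  rec$fs <- fs_target
  rec
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
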