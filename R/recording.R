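# Containers for multichannel EEG recordings and epochs.

#' Construct a multichannel EEG recording
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `samples`.
#' @param subject_id Subject identifier.
#' @param label Class label, `"R"` (responder), `"NR"` (non-responder) or `NA`.
#' @param therapy Therapy tag (e.g. `"SSRI"`, `"rTMS"`, `"synthetic"`).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_labels,
                          subject_id = "S01", label = NA_character_,
                          therapy = NA_character_) {
  samples <- as.matrix(samples)
  assert_scalar_pos(fs, "fs")
  if (nrow(samples) != length(channel_labels))
    stop("`samples` must have one row per entry of `channel_labels`", call. = FALSE)
  if (!is.na(label) && !label %in% c("R", "NR"))
    stop("`label` must be 'R', 'NR' or NA", call. = FALSE)
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels),
                 subject_id = subject_id, label = label, therapy = therapy),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]  %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, ifelse(is.na(x$label), "?", x$label),
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  invisible(x)
}

#' Construct an EEG epoch
#'
#' A fixed-length segment cut from a recording; carries its parent subject id
#' and class label so time-frequency images can be traced back to the subject.
#'
#' @param samples Channels x time numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Channel labels.
#' @param epoch_index 1-based index of the epoch within its recording.
#' @param subject_id,label Propagated from the parent recording.
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(samples, fs, channel_labels, epoch_index,
                      subject_id = "S01", label = NA_character_) {
  samples <- as.matrix(samples)
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels),
                 duration_s = ncol(samples) / fs,
                 epoch_index = as.integer(epoch_index),
                 subject_id = subject_id, label = label),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %s epoch %d [%s]  %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$epoch_index, ifelse(is.na(x$label), "?", x$label),
              nrow(x$samples), ncol(x$samples), x$fs))
  invisible(x)
}
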