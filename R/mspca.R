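# Multiscale PCA denoising of multichannel epochs (multivariate wavelet
# denoising).
#
# Each channel is decomposed with a multilevel periodized sym4 DWT. The noise
# covariance across channels is estimated from the finest-scale detail
# coefficients (median-absolute-deviation variances with the empirical
# correlation structure); its eigenbasis defines the principal directions in
# which the multichannel detail coefficients are expressed at every scale.
# Detail scores are soft-thresholded per direction with the universal
# threshold sigma_i * sqrt(2 log N) and transformed back, so montage-coherent
# activity (which concentrates in few directions with amplified scores) is
# barely shrunk while incoherent noise is removed. Kaiser's retention rule
# (keep eigenvalues above the mean eigenvalue) is applied by PCA across
# channels at the approximation scale and once more to the reconstructed
# signals.

#' MSPCA configuration
#'
#' @param wavelet_name Wavelet identifier (only `"sym4"` is bundled).
#' @param level Decomposition level (default 9).
#' @param threshold_rule Detail thresholding rule (only `"universal"`).
#' @param pc_rule Principal-component retention rule (only `"kaiser"`).
#' @return An object of class `mspca_config`.
#' @export
mspca_config <- function(wavelet_name = "sym4", level = 9L,
                         threshold_rule = "universal", pc_rule = "kaiser") {
  assert_count(level, "level")
  wavelet_name <- match.arg(wavelet_name, "sym4")
  threshold_rule <- match.arg(threshold_rule, "universal")
  pc_rule <- match.arg(pc_rule, "kaiser")
  structure(list(wavelet_name = wavelet_name, level = as.integer(level),
                 threshold_rule = threshold_rule, pc_rule = pc_rule),
            class = "mspca_config")
}

# Kaiser-rule PCA projection across channels: rows of M are channels.
# Returns M projected onto the principal subspace with eigenvalue > mean.
kaiser_pca_project <- function(M) {
  C <- tcrossprod(M) / ncol(M)
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > mean(e$values)
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% crossprod(V, M)
}

# noise covariance across channels from finest-scale details: robust MAD
# variances combined with the empirical correlation structure
noise_covariance <- function(D1) {
  s <- apply(D1, 1L, function(d) stats::median(abs(d)) / 0.6745)
  if (all(s == 0)) return(matrix(0, nrow(D1), nrow(D1)))
  R <- suppressWarnings(stats::cor(t(D1)))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  diag(s) %*% R %*% diag(s)
}

#' Multiscale PCA denoising of an epoch
#'
#' @param epoch An [eeg_epoch()] (or [eeg_recording()]) with at least
#'   `2^level` samples; internally the signal is padded periodically to a
#'   multiple of `2^level` and cropped after reconstruction.
#' @param cfg An [mspca_config()].
#' @return The denoised epoch (same shape).
#' @export
mspca_denoise <- function(epoch, cfg = mspca_config()) {
  stopifnot(inherits(epoch, "eeg_epoch") || inherits(epoch, "eeg_recording"))
  X <- epoch$samples
  n_ch <- nrow(X); n <- ncol(X)
  blk <- 2L^cfg$level
  if (n < blk)
    stop(sprintf("epoch too short for level-%d decomposition: need >= %d samples, got %d",
                 cfg$level, blk, n), call. = FALSE)
  n_pad <- ceiling(n / blk) * blk
  if (n_pad > n) X <- cbind(X, X[, seq_len(n_pad - n), drop = FALSE])
  filt <- sym4_filters()

  decs <- lapply(seq_len(n_ch), function(ch) wavedec_per(X[ch, ], cfg$level, filt))

  # noise covariance across channels, estimated from finest-scale details
  D1 <- do.call(rbind, lapply(decs, function(dc) dc$d[[1L]]))
  Sigma <- noise_covariance(D1)

  # within each scale: rotate the coefficients into their principal
  # directions (PCA across channels), apply the universal soft threshold per
  # direction against the noise level projected into that direction, rotate
  # back; coherent activity concentrates in few directions with amplified
  # scores and is barely shrunk, incoherent noise is removed
  for (j in seq_len(cfg$level)) {
    Dj <- do.call(rbind, lapply(decs, function(dc) dc$d[[j]]))
    Vj <- eigen(tcrossprod(Dj) / ncol(Dj), symmetric = TRUE)$vectors
    S <- crossprod(Vj, Dj)
    sig_dir <- sqrt(pmax(diag(crossprod(Vj, Sigma %*% Vj)), 0))
    thr_dir <- sig_dir * sqrt(2 * log(n_pad))
    for (i in seq_len(n_ch))
      if (thr_dir[i] > 0) S[i, ] <- soft_thresh(S[i, ], thr_dir[i])
    Dj <- Vj %*% S
    for (ch in seq_len(n_ch)) decs[[ch]]$d[[j]] <- Dj[ch, ]
  }

  # Kaiser-rule PCA across channels at the approximation stage
  A <- do.call(rbind, lapply(decs, function(dc) dc$a))
  A <- kaiser_pca_project(A)
  for (ch in seq_len(n_ch)) decs[[ch]]$a <- A[ch, ]

  Y <- do.call(rbind, lapply(decs, function(dc) waverec_per(dc, filt)))
  # Kaiser-rule PCA at the final reconstruction stage
  Y <- kaiser_pca_project(Y)
  epoch$samples <- Y[, seq_len(n), drop = FALSE]
  epoch
}
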