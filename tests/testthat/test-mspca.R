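# Wavelet transform correctness and multiscale PCA denoising behaviour.

test_that("periodized sym4 DWT matches the PyWavelets reference values", {
  # frozen from pywt.dwt((1:16)^1.5, 'sym4', mode='periodization')
  x <- (1:16)^1.5
  dec <- wavedec_per(x, level = 1L)
  expect_equal(dec$a,
               c(-1.32161982286248, 13.4714573754629, 20.8743195339459,
                 32.0959755357544, 44.8250112211671, 58.8991924304899,
                 79.4349194529817, 64.3146372307339), tolerance = 1e-9)
  expect_equal(dec$d[[1L]],
               c(29.6936056671619, -4.87809045670960, -0.00547975494708939,
                 -0.00225300212620336, -0.00118670769761242,
                 -0.000715914468481381, 2.22591290068191, -3.42754942942817),
               tolerance = 1e-9)
})

test_that("multilevel DWT reconstructs perfectly and preserves energy", {
  set.seed(3)
  for (n in c(64L, 256L, 1024L)) {
    x <- rnorm(n)
    lev <- 4L
    dec <- wavedec_per(x, lev)
    expect_equal(waverec_per(dec), x, tolerance = 1e-10)
    # orthogonality: coefficient energy equals signal energy
    e <- sum(dec$a^2) + sum(vapply(dec$d, function(d) sum(d^2), 0))
    expect_equal(e, sum(x^2), tolerance = 1e-8)
  }
  expect_error(wavedec_per(rnorm(100), 3), "divisible")
})

test_that("MSPCA preserves zeros, clean structure, and shape", {
  labels <- paste0("Ch", 1:6)
  zero_ep <- eeg_epoch(matrix(0, 6, 1024), 256, labels, 1L)
  out <- mspca_denoise(zero_ep, mspca_config(level = 5))
  expect_equal(out$samples, zero_ep$samples)
  expect_identical(dim(out$samples), c(6L, 1024L))

  # noiseless multichannel sinusoids at EEG rhythm frequencies (delta,
  # theta, alpha) survive almost untouched
  fs <- 256
  t <- (0:2047) / fs
  S <- rbind(sin(2 * pi * 3 * t), sin(2 * pi * 7 * t), sin(2 * pi * 13 * t))
  X <- S[rep(1:3, each = 2), ] * rep(c(1, 0.9), 3)
  ep <- eeg_epoch(X, fs, labels, 1L)
  den <- mspca_denoise(ep, mspca_config(level = 5))
  rel <- sqrt(sum((den$samples - X)^2)) / sqrt(sum(X^2))
  expect_lt(rel, 0.05)

  expect_error(mspca_denoise(eeg_epoch(matrix(0, 3, 100), 256, labels[1:3], 1L),
                             mspca_config(level = 9)), "512")
})

test_that("MSPCA improves the SNR of a shared tone in channel noise", {
  set.seed(9)
  fs <- 256
  n <- 4096
  t <- (0:(n - 1)) / fs
  clean <- sin(2 * pi * 10 * t)
  amps <- runif(19, 0.8, 1.2)
  X_clean <- outer(amps, clean)
  noise <- matrix(rnorm(19 * n, sd = sqrt(mean(clean^2))), 19)  # ~0 dB SNR
  ep <- eeg_epoch(X_clean + noise, fs, montage_1020(), 1L)
  den <- mspca_denoise(ep, mspca_config(level = 9))
  snr <- function(Y) 10 * log10(sum(X_clean^2) / sum((Y - X_clean)^2))
  expect_gt(snr(den$samples) - snr(ep$samples), 3)
})
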