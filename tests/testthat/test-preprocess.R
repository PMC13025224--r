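# Filtering, re-referencing and epoch segmentation.

make_rec <- function(X, fs = 256, labels = paste0("Ch", seq_len(nrow(X))))
  eeg_recording(X, fs, labels, subject_id = "T01", label = "R")

test_that("band-pass removes DC and passes/notches the right frequencies", {
  fs <- 256
  t <- (0:(30 * fs - 1)) / fs
  core <- (12 * fs):(18 * fs)            # steady-state window
  X <- rbind(rep(5, length(t)),          # DC
             sin(2 * pi * 10 * t),       # in-band tone
             sin(2 * pi * 50 * t))       # mains
  out <- bandpass_notch(make_rec(X, fs), low = 0.5, high = 70, notch = 50)$samples
  expect_lt(max(abs(out[1, core])), 0.01 * 5)
  rms <- function(v) sqrt(mean(v^2))
  expect_gt(rms(out[2, core]) / rms(X[2, core]), 0.95)
  expect_lt(rms(out[2, core]) / rms(X[2, core]), 1.05)
  expect_lt(rms(out[3, core]) / rms(X[3, core]), 0.1)
})

test_that("filtering is zero-phase (no group delay on a tone)", {
  fs <- 256
  t <- (0:(6 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  y <- bandpass_notch(make_rec(rbind(x), fs))$samples[1, ]
  core <- (fs):(5 * fs)
  cc <- stats::ccf(y[core], x[core], lag.max = 10, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("band edge above Nyquist is rejected", {
  expect_error(bandpass_notch(make_rec(matrix(rnorm(512), 2), fs = 128),
                              high = 70), "Nyquist")
})

test_that("common average reference matches its closed form and is idempotent", {
  set.seed(1)
  X <- matrix(rnorm(5 * 100), 5)
  out <- common_average_reference(make_rec(X))$samples
  expect_lt(max(abs(colMeans(out))), 1e-10)
  # two channels [a, b] -> [(a-b)/2, (b-a)/2]
  ab <- matrix(rnorm(2 * 50), 2)
  out2 <- common_average_reference(make_rec(ab))$samples
  expect_equal(out2[1, ], (ab[1, ] - ab[2, ]) / 2)
  expect_equal(out2[2, ], (ab[2, ] - ab[1, ]) / 2)
  # idempotence
  expect_equal(common_average_reference(make_rec(out))$samples, out)
  expect_error(common_average_reference(make_rec(matrix(1:10, 1))), "2 channels")
})

test_that("epoch segmentation is exhaustive, non-overlapping and floors", {
  fs <- 64
  rec <- make_rec(matrix(rnorm(3 * 300 * fs), 3), fs)
  eps <- segment_epochs(rec, win_s = 15)
  expect_length(eps, 20L)
  expect_true(all(vapply(eps, function(e) ncol(e$samples), 0L) == 15 * fs))
  # concatenating epochs reproduces the first floor(T/15)*15 seconds
  cat_samples <- do.call(cbind, lapply(eps, `[[`, "samples"))
  expect_identical(cat_samples, rec$samples[, 1:(20 * 15 * fs)])
  # 29-s recording -> exactly 1 epoch
  short <- make_rec(matrix(rnorm(2 * 29 * fs), 2), fs)
  expect_length(segment_epochs(short, 15), 1L)
  # shorter than one window -> empty with warning
  expect_warning(out <- segment_epochs(make_rec(matrix(rnorm(2 * 64), 2), fs), 15),
                 "shorter")
  expect_length(out, 0L)
})

test_that("amplitude rejection drops exactly the spiking epochs", {
  fs <- 32
  X <- matrix(rnorm(2 * 150 * fs, sd = 10), 2)
  X[1, 4 * 15 * fs + 5L] <- 500          # spike inside epoch 5
  rec <- make_rec(X, fs)
  eps <- segment_epochs(rec, 15, reject_amplitude_uv = 300)
  expect_length(eps, 9L)
  expect_identical(attr(eps, "n_rejected"), 1L)
  expect_false(5L %in% vapply(eps, `[[`, 0L, "epoch_index"))
  # oracle: direct max-abs scan
  keep <- vapply(1:10, function(i)
    max(abs(X[, ((i - 1) * 15 * fs + 1):(i * 15 * fs)])) <= 300, logical(1))
  expect_identical(vapply(eps, `[[`, 0L, "epoch_index"), which(keep))
})

test_that("resampling changes the rate and preserves a tone", {
  fs <- 256
  t <- (0:(4 * fs - 1)) / fs
  rec <- make_rec(rbind(sin(2 * pi * 8 * t)), fs)
  up <- resample_recording(rec, 512)
  expect_equal(up$fs, 512)
  expect_equal(ncol(up$samples), 2 * ncol(rec$samples))
  sp <- Mod(stats::fft(up$samples[1, ]))[1:1024]
  f <- (0:1023) * 512 / ncol(up$samples)
  expect_lt(abs(f[which.max(sp)] - 8), 0.3)
})
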