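# Scalograms, spectrograms, normalisation, fusion and rendering.

tone_img <- function(f0 = 10, fs = 256, dur = 4, cfg = cwt_config(fmax = 60)) {
  x <- as.numeric(generate_tones(tone_spec(f0, duration_s = dur, fs = fs)))
  cwt_scalogram(x, fs, cfg, channel_label = "O1", subject_id = "S01",
                epoch_index = 1L)
}

test_that("scalogram peaks at the tone frequency and is homogeneous", {
  img <- tone_img(10)
  peak_f <- img$freq_axis[which.max(rowMeans(img$values))]
  expect_lt(abs(log2(peak_f / 10)), 1 / 12)         # within half a voice
  # zero signal -> zero image; doubling input doubles magnitudes
  z <- cwt_scalogram(rep(0, 512), 256, cwt_config())
  expect_equal(max(z$values), 0)
  x <- as.numeric(generate_tones(tone_spec(10, duration_s = 2, fs = 256)))
  a <- cwt_scalogram(x, 256, cwt_config())
  b <- cwt_scalogram(2 * x, 256, cwt_config())
  expect_equal(b$values, 2 * a$values, tolerance = 1e-12)
})

test_that("scalogram energy localises within one voice of the tone row", {
  img <- tone_img(12, dur = 6)
  E <- rowSums(img$values^2)
  pk <- which.max(E)
  sel <- abs(log2(img$freq_axis / img$freq_axis[pk])) <= 1 / 12 + 1e-9
  expect_gte(sum(E[sel]) / sum(E), 0.5)
})

test_that("fmax above Nyquist is clipped with a warning", {
  expect_warning(img <- cwt_scalogram(rnorm(256), 64, cwt_config(fmax = 60)),
                 "Nyquist")
  expect_lte(max(img$freq_axis), 32)
})

test_that("STFT has the configured hop and localises a tone to its bin", {
  cfg <- stft_config()     # defaults: window 256, overlap 250, nfft 7680
  expect_identical(cfg$hop, 6L)
  y <- as.numeric(generate_tones(tone_spec(20, duration_s = 2, fs = 512)))
  S <- stft_spectrogram(y, cfg)
  f <- attr(S, "f")
  pk <- f[which.max(rowMeans(Mod(unclass(S))))]
  expect_lte(abs(pk - 20), 512 / 7680)
  z <- stft_spectrogram(rep(0, 600), cfg)
  expect_equal(max(Mod(unclass(z))), 0)
  expect_error(stft_spectrogram(rnorm(100), cfg), "shorter")
})

test_that("STFT agrees with signal::specgram on a common configuration", {
  set.seed(2)
  x <- rnorm(1024)
  cfg <- stft_config(win_len = 128, overlap = 64, nfft = 256, fs = 256)
  mine <- unclass(stft_spectrogram(x, cfg))
  ref <- signal::specgram(x, n = 256, Fs = 256,
                          window = signal::hamming(128), overlap = 64)
  # specgram returns nfft/2 rows (no Nyquist bin) and may drop the last
  # frame; compare the shared block
  ri <- seq_len(nrow(ref$S)); ci <- seq_len(ncol(ref$S))
  expect_gte(ncol(mine), ncol(ref$S))
  expect_lt(max(Mod(mine[ri, ci] - ref$S)) / max(Mod(ref$S)), 1e-10)
})

test_that("aggregate spectrogram equals the spectrogram of the sum", {
  set.seed(4)
  cfg <- stft_config(win_len = 64, overlap = 58, nfft = 128, fs = 256,
                     fmax_display = 60)
  for (K in c(1L, 3L, 7L)) {
    modes <- matrix(rnorm(K * 500), K)
    agg <- aggregate_vmd_spectrogram(modes, cfg)
    ref <- stft_spectrogram(colSums(modes), cfg)
    keep <- attr(ref, "f") <= 60
    expect_lt(max(abs(agg$values - Mod(unclass(ref))[keep, ])) /
                max(agg$values), 1e-10)
  }
  expect_error(aggregate_vmd_spectrogram(matrix(numeric(0), 0, 10)), "one mode")
})

test_that("VMD modes of a two-tone signal yield ridges at the tone rows", {
  x <- as.numeric(generate_tones(tone_spec(c(8, 40), duration_s = 4, fs = 256)))
  dec <- vmd_decompose(x, 256, vmd_config(K = 2))
  cfg <- stft_config(win_len = 128, overlap = 120, nfft = 512, fs = 256)
  img <- aggregate_vmd_spectrogram(dec$modes, cfg)
  prof <- rowMeans(img$values)
  # local maxima of the frequency profile sit at the tones
  top2 <- img$freq_axis[order(prof, decreasing = TRUE)[1:2]]
  expect_lt(min(abs(top2 - 8)), 1)
  expect_lt(min(abs(top2 - 40)), 1)
})

test_that("min-max normalisation matches its closed form and guards", {
  m <- matrix(c(1, 5, 3, 9), 2)
  expect_equal(minmax_normalise(m), matrix(c(0, 0.5, 0.25, 1), 2))
  u <- matrix(c(0, 0.2, 1, 0.4), 2)
  expect_equal(minmax_normalise(u), u)
  expect_warning(z <- minmax_normalise(matrix(7, 3, 3)), "constant")
  expect_equal(z, matrix(0, 3, 3))
})

test_that("fusion averages normalised inputs and respects bounds", {
  img <- tone_img(10)
  x <- as.numeric(generate_tones(tone_spec(10, duration_s = 4, fs = 256)))
  vcfg <- stft_config(win_len = 64, overlap = 56, nfft = 256, fs = 256)
  vimg <- aggregate_vmd_spectrogram(matrix(x, 1), vcfg, channel_label = "O1",
                                    subject_id = "S01", epoch_index = 1L)
  fu <- fuse(img, vimg, size = 64)
  expect_identical(fu$repr, "FUSION")
  expect_true(all(fu$values >= 0 & fu$values <= 1))
  # element-wise between the two normalised sources
  A <- minmax_normalise(eegtfr:::resize_bilinear(img$values, 64, 64))
  B <- minmax_normalise(eegtfr:::resize_bilinear(vimg$values, 64, 64))
  expect_true(all(fu$values >= pmin(A, B) - 1e-12))
  expect_true(all(fu$values <= pmax(A, B) + 1e-12))
  # fuse(X, X) = minmax(X)
  self_fu <- fuse(img, img)
  expect_equal(self_fu$values, minmax_normalise(img)$values, tolerance = 1e-12)
  # metadata mismatch is named
  other <- vimg; other$subject_id <- "S02"
  expect_error(fuse(img, other), "subject_id")
})

test_that("rendering produces square jet RGB with correct endpoints", {
  img <- tone_img(10)
  path <- tempfile(fileext = ".png")
  arr <- render_png(img, path = path, size = 224)
  expect_identical(dim(arr), c(224L, 224L, 3L))
  expect_true(file.exists(path))
  on_disk <- png::readPNG(path)
  expect_identical(dim(on_disk), c(224L, 224L, 3L))
  # LUT endpoints: min -> dark blue, max -> dark red
  lut <- jet_colormap()
  expect_equal(lut[1, ], c(0, 0, 0.5), ignore_attr = TRUE)
  expect_equal(lut[256, ], c(0.5, 0, 0), ignore_attr = TRUE)
  # constant image renders as a uniform single colour
  const <- tf_image(matrix(1, 4, 4), 1:4, 1:4, "CWT")
  cr <- render_png(const, size = 4)
  expect_equal(max(abs(sweep(cr, 3, cr[1, 1, ]))), 0)
})

test_that("file names round-trip image metadata", {
  img <- tone_img(10)
  fn <- tf_filename(img)
  expect_identical(fn, "S01_1_O1_CWT.png")
  meta <- parse_tf_filename(fn)
  expect_identical(meta$subject_id, "S01")
  expect_identical(meta$epoch_index, 1L)
  expect_identical(meta$channel_label, "O1")
  expect_identical(meta$repr, "CWT")
  # subject ids containing underscores survive
  img$subject_id <- "site_A_S07"
  expect_identical(parse_tf_filename(tf_filename(img))$subject_id, "site_A_S07")
})
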