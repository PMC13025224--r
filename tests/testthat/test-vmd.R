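# Variational mode decomposition: tone recovery, reconstruction, fixed-point
# behaviour, oracle equivalence and the spectral centroid.

test_that("VMD recovers two-tone centre frequencies and reconstructs", {
  x <- as.numeric(generate_tones(tone_spec(c(5, 40), duration_s = 15, fs = 512)))
  res <- vmd_decompose(x, 512, vmd_config(K = 2, alpha = 2000))
  expect_true(res$converged)
  expect_equal(dim(res$modes), c(2L, length(x)))
  expect_false(is.unsorted(res$omegas))
  expect_true(all(res$omegas >= 0 & res$omegas <= 0.5))
  expect_lt(max(abs(res$omegas_hz - c(5, 40))), 0.5)
  expect_lt(res$residual, 0.05)
})

test_that("a zero signal is a fixed point reached immediately", {
  res <- vmd_decompose(rep(0, 200), 100, vmd_config(K = 3))
  expect_true(res$converged)
  expect_lte(res$n_iter, 2L)
  expect_equal(max(abs(res$modes)), 0)
})

test_that("converged modes satisfy the update fixed point", {
  x <- as.numeric(generate_tones(tone_spec(c(8, 30), duration_s = 4, fs = 256)))
  cfg <- vmd_config(K = 2, alpha = 2000, tol = 1e-9)
  res <- vmd_decompose(x, 256, cfg)
  # one further full update pass changes each mode only marginally
  res2 <- vmd_decompose(x, 256, vmd_config(K = 2, alpha = 2000, tol = 1e-12,
                                           max_iter = res$n_iter + 1L))
  rel <- vapply(1:2, function(k)
    sqrt(sum((res2$modes[k, ] - res$modes[k, ])^2) / sum(res$modes[k, ]^2)),
    numeric(1))
  expect_lt(max(rel), 10 * 1e-6)
})

test_that("larger alpha narrows the spectral spread of every mode", {
  x <- as.numeric(generate_tones(tone_spec(c(10, 35), duration_s = 4, fs = 256)))
  spread <- function(alpha) {
    r <- vmd_decompose(x, 256, vmd_config(K = 2, alpha = alpha))
    vapply(1:2, function(k) {
      s <- Mod(stats::fft(r$modes[k, ]))[1:513]^2
      f <- (0:512) / 1024
      mu <- sum(f * s) / sum(s)
      sum((f - mu)^2 * s) / sum(s)
    }, numeric(1))
  }
  sps <- vapply(c(500, 2000, 8000), spread, numeric(2))
  expect_true(all(diff(t(sps))[, 1] <= 1e-12))
  expect_true(all(diff(t(sps))[, 2] <= 1e-12))
})

test_that("solver agrees with the naive direct-iteration reference", {
  set.seed(5)
  t <- (0:999) / 250
  x <- cos(2 * pi * 7 * t) + 0.7 * cos(2 * pi * 45 * t)
  res <- vmd_decompose(x, 250, vmd_config(K = 2, alpha = 2000, tol = 1e-7,
                                          max_iter = 300))
  ref <- naive_vmd(x, K = 2, alpha = 2000, tol = 1e-7, max_iter = 300)
  expect_equal(res$n_iter, ref$n_iter)
  expect_equal(res$omegas, ref$om, tolerance = 1e-9)
  # compare reconstructed modes in the time domain
  n <- 2 * length(x)
  for (k in 1:2) {
    full <- eegtfr:::one_sided_to_full(ref$U[k, ], n)
    mk <- Re(stats::fft(full, inverse = TRUE))[501:1500] / n
    rel <- sqrt(sum((res$modes[k, ] - mk)^2) / sum(mk^2))
    expect_lt(rel, 1e-6)
  }
})

test_that("mode ordering is canonical under permuted initial frequencies", {
  x <- as.numeric(generate_tones(tone_spec(c(6, 50), duration_s = 4, fs = 256)))
  init <- seq(0, 0.25, length.out = 3)
  a <- vmd_decompose(x, 256, vmd_config(K = 3, init_omegas = init,
                                        max_iter = 3000))
  b <- vmd_decompose(x, 256, vmd_config(K = 3, init_omegas = rev(init),
                                        max_iter = 3000))
  expect_equal(a$omegas_hz, b$omegas_hz, tolerance = 0.1)
  expect_false(is.unsorted(a$omegas))
  expect_false(is.unsorted(b$omegas))
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(vmd_decompose(c(1, NA, 3), 10, vmd_config(K = 1)), "finite")
  expect_error(vmd_decompose(rnorm(10), 10, vmd_config(K = 8)), "twice")
  expect_warning(vmd_decompose(rnorm(256), 128,
                               vmd_config(K = 3, max_iter = 2)), "converge")
})

test_that("spectral centroid matches point-mass, symmetry and Gaussian cases", {
  f <- seq(0, 50, by = 0.5)
  s <- rep(0, length(f)); s[f == 10] <- 1
  expect_equal(spectral_centroid(s, f), 10)
  s2 <- rep(0, length(f)); s2[f == 10] <- 1; s2[f == 20] <- 1
  expect_equal(spectral_centroid(s2, f), 15)
  g <- exp(-0.5 * ((f - 12) / 2)^2)
  expect_lt(abs(spectral_centroid(g, f) - 12), 0.1)
  expect_warning(z <- spectral_centroid(rep(0, length(f)), f), "zero")
  expect_equal(z, 0)
  expect_error(spectral_centroid(c(-1, 1), c(0, 1)), "non-negative")
})
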