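# Periodized orthogonal discrete wavelet transform (sym4 by default).
#
# A compact multilevel DWT/IDWT with circular (periodized) boundary handling,
# the same convention as PyWavelets' mode = "periodization": at each level the
# analysis output is
#   a[k] = sum_m h[m] x[(2k + L/2 - m) mod N],   k = 0..N/2-1  (0-based)
# with L the filter length, which is orthogonal and perfectly invertible for
# even N. Only the filters needed by the denoiser are bundled.

# Symlet-4 decomposition filters (orthogonal; reconstruction = time-reversal)
sym4_filters <- function() {
  lo <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
          0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
          -0.01260396726203783, 0.03222310060404270)
  hi <- rev(lo) * c(-1, 1, -1, 1, -1, 1, -1, 1)
  list(lo = lo, hi = hi)
}

dwt_step <- function(x, filt) {
  n <- length(x)
  if (n %% 2L != 0L) stop("periodized DWT step requires even length", call. = FALSE)
  L <- length(filt$lo)
  half <- n %/% 2L
  k <- 0:(half - 1L)
  a <- numeric(half); d <- numeric(half)
  for (m in 0:(L - 1L)) {
    idx <- (2L * k + L %/% 2L - m) %% n + 1L
    a <- a + filt$lo[m + 1L] * x[idx]
    d <- d + filt$hi[m + 1L] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, filt) {
  half <- length(a)
  n <- 2L * half
  L <- length(filt$lo)
  x <- numeric(n)
  k <- 0:(half - 1L)
  for (m in 0:(L - 1L)) {
    idx <- (2L * k + L %/% 2L - m) %% n + 1L
    x[idx] <- x[idx] + filt$lo[m + 1L] * a + filt$hi[m + 1L] * d
  }
  x
}

#' Multilevel periodized wavelet decomposition
#'
#' @param x Numeric vector whose length is divisible by `2^level`.
#' @param level Number of decomposition levels.
#' @param filters Analysis filter pair (default Symlet-4).
#' @return List with `a` (coarsest approximation) and `d` (list of detail
#'   vectors, `d[[1]]` = finest).
#' @export
wavedec_per <- function(x, level, filters = sym4_filters()) {
  assert_count(level, "level")
  if (length(x) %% 2L^level != 0L)
    stop(sprintf("length(x) = %d must be divisible by 2^level = %d",
                 length(x), 2L^level), call. = FALSE)
  d <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- dwt_step(a, filters)
    a <- s$a
    d[[j]] <- s$d
  }
  list(a = a, d = d)
}

#' Multilevel periodized wavelet reconstruction
#'
#' Inverse of [wavedec_per()].
#'
#' @param dec Decomposition as returned by [wavedec_per()].
#' @param filters Filter pair used for the decomposition.
#' @return Reconstructed numeric vector.
#' @export
waverec_per <- function(dec, filters = sym4_filters()) {
  a <- dec$a
  for (j in rev(seq_along(dec$d))) a <- idwt_step(a, dec$d[[j]], filters)
  a
}

# soft threshold
soft_thresh <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)
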