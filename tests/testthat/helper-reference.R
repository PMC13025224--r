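# Independent reference implementations used as test oracles.

# Naive VMD: the same alternating spectral updates written as plain loops,
# kept deliberately free of the solver's vectorisation and bookkeeping so it
# can serve as an independent check of the production implementation.
naive_vmd <- function(x, K, alpha, tau = 0, tol = 1e-7, max_iter = 500L,
                      mirror = TRUE) {
  n0 <- length(x)
  if (mirror) {
    half <- floor(n0 / 2)
    x <- c(rev(x[1:half]), x, rev(x[(n0 - half + 1):n0]))
  }
  n <- length(x)
  nh <- n %/% 2 + 1
  om_axis <- (0:(nh - 1)) / n
  xf <- stats::fft(x)[1:nh]
  U <- matrix(0 + 0i, K, nh)
  lam <- rep(0 + 0i, nh)
  om <- if (K == 1) 0.125 else seq(0, 0.25, length.out = K)
  for (it in seq_len(max_iter)) {
    change <- 0
    for (k in seq_len(K)) {
      others <- rep(0 + 0i, nh)
      for (j in seq_len(K)) if (j != k) others <- others + U[j, ]
      unew <- rep(0 + 0i, nh)
      for (w in seq_len(nh)) {
        unew[w] <- (xf[w] - others[w] + lam[w] / 2) /
          (1 + 2 * alpha * (om_axis[w] - om[k])^2)
      }
      num <- 0; den <- 0
      for (w in seq_len(nh)) {
        pw <- Mod(unew[w])^2
        num <- num + om_axis[w] * pw
        den <- den + pw
      }
      om[k] <- if (den > 0) num / den else 0
      change <- change + sum(Mod(unew - U[k, ])^2) /
        (sum(Mod(U[k, ])^2) + .Machine$double.eps)
      U[k, ] <- unew
    }
    if (tau != 0) {
      tot <- rep(0 + 0i, nh)
      for (k in seq_len(K)) tot <- tot + U[k, ]
      lam <- lam + tau * (xf - tot)
    }
    if (change < tol) break
  }
  ord <- order(om)
  list(U = U[ord, , drop = FALSE], om = om[ord], n_iter = it)
}

# brute-force metric recount from raw (truth, prediction) label pairs
brute_metrics <- function(truth, pred) {
  tp <- sum(truth == "R" & pred == "R"); tn <- sum(truth == "NR" & pred == "NR")
  fp <- sum(truth == "NR" & pred == "R"); fn <- sum(truth == "R" & pred == "NR")
  pr <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  rc <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  c(accuracy = 100 * (tp + tn) / length(truth),
    precision = pr, recall = rc,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else 0,
    f1 = if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0)
}

# Welch band power via stats::spec.pgram smoothing-free periodogram average
welch_band_power <- function(x, fs, lo, hi, seg_s = 4) {
  seg <- round(seg_s * fs)
  n_seg <- floor(length(x) / seg)
  ps <- rep(0, seg %/% 2)
  for (i in seq_len(n_seg)) {
    s <- x[((i - 1) * seg + 1):(i * seg)]
    s <- s - mean(s)
    sp <- Mod(stats::fft(s * 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / (seg - 1)))))^2
    ps <- ps + sp[1:(seg %/% 2)]
  }
  f <- (0:(seg %/% 2 - 1)) * fs / seg
  mean(ps[f >= lo & f <= hi]) / n_seg
}

# tiny labelled image set with a controllable intensity offset per class
make_toy_images <- function(n_per_class, size = 16, gap = 0.4, seed = 1) {
  set.seed(seed)
  labs <- rep(c("R", "NR"), each = n_per_class)
  imgs <- lapply(labs, function(cl) {
    base <- if (cl == "R") 0.5 + gap / 2 else 0.5 - gap / 2
    array(pmin(pmax(base + runif(size * size * 3, -0.15, 0.15), 0), 1),
          c(size, size, 3))
  })
  image_set(imgs, labs)
}
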