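# Exact Wilcoxon signed-rank comparison of per-fold accuracies.
#
# With only six folds per comparison the normal approximation is far from
# valid, so the null distribution of the signed-rank statistic is enumerated
# exactly over all 2^n sign assignments. Zero differences are dropped first
# (standard signed-rank convention) and tied absolute differences receive
# average ranks, which the enumeration handles transparently.

#' Exact two-sided Wilcoxon signed-rank test for paired samples
#'
#' @param x,y Paired numeric vectors (e.g. per-fold accuracies of two
#'   models).
#' @param max_exact Largest number of non-zero differences for which the
#'   exact enumeration is used; beyond it a tie-corrected normal
#'   approximation with continuity correction is applied.
#' @return List with `statistic` (V, sum of ranks of positive differences),
#'   `p_value` (two-sided), `n_used` (non-zero pairs) and `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y, max_exact = 20L) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_used = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= max_exact) {
    # enumerate the null: every subset of ranks is equally likely positive
    stats_all <- numeric(2^n)
    idx <- 0L
    for (mask in 0:(2^n - 1L)) {
      idx <- idx + 1L
      stats_all[idx] <- sum(r[bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L])
    }
    mu <- n * (n + 1) / 4
    p <- mean(abs(stats_all - mu) >= abs(v - mu) - 1e-12)
    return(list(statistic = v, p_value = min(1, p), n_used = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_sizes <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_sizes^3 - tie_sizes) / 48
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  list(statistic = v, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       n_used = n, exact = FALSE)
}

#' Pairwise signed-rank comparison of a fold-accuracy table
#'
#' Runs the exact two-sided Wilcoxon signed-rank test on every unordered
#' pair of rows (models or representations) of a per-fold accuracy matrix.
#'
#' @param acc_table Numeric matrix, rows = models (named), columns = folds.
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame with one row per pair: `a`, `b`, `statistic`,
#'   `p_value`, `significant`.
#' @export
wilcoxon_pairwise <- function(acc_table, alpha = 0.05) {
  acc_table <- as.matrix(acc_table)
  if (ncol(acc_table) < 5L)
    stop("need at least 5 paired folds per comparison", call. = FALSE)
  nm <- rownames(acc_table)
  if (is.null(nm)) nm <- paste0("model", seq_len(nrow(acc_table)))
  pairs <- utils::combn(nrow(acc_table), 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    w <- suppressWarnings(wilcoxon_signed_rank(acc_table[i1, ], acc_table[i2, ]))
    data.frame(a = nm[i1], b = nm[i2], statistic = w$statistic,
               p_value = w$p_value, significant = w$p_value < alpha,
               stringsAsFactors = FALSE)
  }))
  out
}
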