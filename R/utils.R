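# Internal helpers shared across modules.

#' Standard 19-electrode 10-20 montage labels
#'
#' Channel labels of the classic 19-electrode international 10-20 placement,
#' in the conventional anterior-to-posterior order.
#'
#' @return Character vector of length 19.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

# scalar-validation helpers ----------------------------------------------

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

#' Derive a deterministic stage seed from a global seed
#'
#' Mixes a global integer seed with a stage name so that every pipeline stage
#' draws from its own reproducible stream and partial re-runs stay consistent
#' with full runs.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 2654435L + h * 97L) %% .Machine$integer.max)
}

# bilinear resampling of a numeric matrix onto a new grid (pixel-centre
# alignment, edges clamped)
resize_bilinear <- function(m, nrow_out, ncol_out) {
  nr <- nrow(m); nc <- ncol(m)
  src_coord <- function(n_out, n_in) {
    u <- ((seq_len(n_out) - 0.5) * n_in / n_out) + 0.5 - 1
    pmin(pmax(u, 0), n_in - 1)
  }
  ry <- src_coord(nrow_out, nr)
  rx <- src_coord(ncol_out, nc)
  y0 <- pmin(floor(ry), nr - 2); y1 <- y0 + 1; wy <- ry - y0
  x0 <- pmin(floor(rx), nc - 2); x1 <- x0 + 1; wx <- rx - x0
  if (nr == 1L) { y0 <- y1 <- rep(0, nrow_out); wy <- rep(0, nrow_out) }
  if (nc == 1L) { x0 <- x1 <- rep(0, ncol_out); wx <- rep(0, ncol_out) }
  i00 <- outer(y0 + 1, (x0) * nr, `+`); i10 <- outer(y1 + 1, (x0) * nr, `+`)
  i01 <- outer(y0 + 1, (x1) * nr, `+`); i11 <- outer(y1 + 1, (x1) * nr, `+`)
  WY <- matrix(wy, nrow_out, ncol_out)
  WX <- matrix(wx, nrow_out, ncol_out, byrow = TRUE)
  v <- as.vector(m)
  out <- (1 - WY) * (1 - WX) * v[i00] + WY * (1 - WX) * v[i10] +
    (1 - WY) * WX * v[i01] + WY * WX * v[i11]
  matrix(out, nrow_out, ncol_out)
}
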