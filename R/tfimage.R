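# Time-frequency image container, normalisation, fusion and PNG rendering.

#' Construct a time-frequency image
#'
#' @param values Non-negative numeric matrix (frequency rows x time columns)
#'   of magnitudes; fusion images hold values in `[0, 1]`.
#' @param time_axis Time axis in seconds (length `ncol(values)`).
#' @param freq_axis Monotone frequency axis in Hz (length `nrow(values)`).
#' @param repr Representation tag: `"CWT"`, `"VMD"` or `"FUSION"`.
#' @param channel_label,subject_id,epoch_index Provenance metadata.
#' @return An object of class `tf_image`.
#' @export
tf_image <- function(values, time_axis, freq_axis,
                     repr = c("CWT", "VMD", "FUSION"),
                     channel_label = NA_character_, subject_id = NA_character_,
                     epoch_index = NA_integer_) {
  repr <- match.arg(repr)
  values <- as.matrix(values)
  if (length(freq_axis) != nrow(values) || length(time_axis) != ncol(values))
    stop("axis lengths must match image dimensions", call. = FALSE)
  if (is.unsorted(freq_axis) && is.unsorted(rev(freq_axis)))
    stop("`freq_axis` must be monotone", call. = FALSE)
  if (any(values < 0)) stop("`values` must be non-negative", call. = FALSE)
  structure(list(values = values, time_axis = time_axis, freq_axis = freq_axis,
                 repr = repr, channel_label = channel_label,
                 subject_id = subject_id, epoch_index = as.integer(epoch_index)),
            class = "tf_image")
}

#' @export
print.tf_image <- function(x, ...) {
  cat(sprintf("<tf_image %s> %d freq x %d time  [%g, %g] Hz  %s/%s/ep%s\n",
              x$repr, nrow(x$values), ncol(x$values),
              min(x$freq_axis), max(x$freq_axis),
              x$subject_id, x$channel_label, x$epoch_index))
  invisible(x)
}

#' Min-max normalisation of an image to the unit interval
#'
#' `(I - min) / (max - min)` over all pixels. A constant image (max = min)
#' maps to all zeros with a warning (division-by-zero guard).
#'
#' @param img A [tf_image()] (or plain numeric matrix).
#' @return Object of the same kind with values in `[0, 1]`.
#' @export
minmax_normalise <- function(img) {
  v <- if (inherits(img, "tf_image")) img$values else as.matrix(img)
  if (any(!is.finite(v))) stop("image contains non-finite values", call. = FALSE)
  rng <- range(v)
  if (rng[2] == rng[1]) {
    warning("constant image; min-max normalisation returns all zeros")
    v[] <- 0
  } else {
    v <- (v - rng[1]) / (rng[2] - rng[1])
  }
  if (inherits(img, "tf_image")) { img$values <- v; img } else v
}

#' Pixel-wise fusion of a CWT and a VMD image
#'
#' Both images must describe the same subject, epoch and channel. They are
#' bilinearly resampled to a common `size x size` grid (their native grids
#' differ), independently min-max normalised, and averaged pixel-wise:
#' `I_fused = (I_cwt + I_vmd) / 2`, which stays in `[0, 1]` and weights the
#' two representations equally.
#'
#' @param cwt_img,vmd_img [tf_image()] objects to fuse.
#' @param size Common grid edge length in pixels (default 224). When the two
#'   inputs already share a grid it is kept as-is.
#' @return A [tf_image()] with `repr = "FUSION"`.
#' @export
fuse <- function(cwt_img, vmd_img, size = 224L) {
  stopifnot(inherits(cwt_img, "tf_image"), inherits(vmd_img, "tf_image"))
  for (key in c("subject_id", "epoch_index", "channel_label")) {
    a <- cwt_img[[key]]; b <- vmd_img[[key]]
    if (!identical(is.na(a), is.na(b)) || (!is.na(a) && !identical(a, b)))
      stop(sprintf("cannot fuse: images disagree on `%s` (%s vs %s)", key, a, b),
           call. = FALSE)
  }
  A <- cwt_img$values; B <- vmd_img$values
  if (!identical(dim(A), dim(B))) {
    A <- resize_bilinear(A, size, size)
    B <- resize_bilinear(B, size, size)
  }
  A <- minmax_normalise(A)
  B <- minmax_normalise(B)
  fused <- (A + B) / 2
  tf_image(fused,
           time_axis = seq(min(cwt_img$time_axis), max(cwt_img$time_axis),
                           length.out = ncol(fused)),
           freq_axis = seq(min(cwt_img$freq_axis), max(cwt_img$freq_axis),
                           length.out = nrow(fused)),
           repr = "FUSION", channel_label = cwt_img$channel_label,
           subject_id = cwt_img$subject_id, epoch_index = cwt_img$epoch_index)
}

#' 256-level jet colour lookup table
#'
#' The classic jet map running from dark blue through cyan, yellow and red to
#' dark red.
#'
#' @param n Number of levels (default 256).
#' @return `n x 3` matrix of RGB values in `[0, 1]`.
#' @export
jet_colormap <- function(n = 256L) {
  u <- seq(0, 1, length.out = n)
  ramp <- function(x) pmin(pmax(x, 0), 1)
  r <- ramp(1.5 - abs(4 * u - 3))
  g <- ramp(1.5 - abs(4 * u - 2))
  b <- ramp(1.5 - abs(4 * u - 1))
  cbind(r, g, b)
}

# map a [0,1] matrix through the jet LUT -> H x W x 3 array
apply_jet <- function(v, lut = jet_colormap()) {
  idx <- pmin(pmax(floor(v * (nrow(lut) - 1L)) + 1L, 1L), nrow(lut))
  out <- array(0, c(nrow(v), ncol(v), 3L))
  for (c in 1:3) out[, , c] <- matrix(lut[idx, c], nrow(v), ncol(v))
  out
}

#' Render a time-frequency image as a square RGB array / PNG file
#'
#' Raw magnitudes are min-max normalised to `[0, 1]` (no log compression),
#' mapped through a 256-level jet lookup table with low frequencies at the
#' bottom row, bilinearly resized to `size x size`, and optionally written as
#' a borderless 8-bit RGB PNG.
#'
#' @param img A [tf_image()].
#' @param path Output PNG path, or `NULL` to return the array only.
#' @param size Output edge length in pixels (default 224).
#' @return `size x size x 3` RGB array in `[0, 1]`, invisibly when written.
#' @export
render_png <- function(img, path = NULL, size = 224L) {
  stopifnot(inherits(img, "tf_image"))
  v <- suppressWarnings(minmax_normalise(img$values))
  # orient with frequency increasing upwards (row 1 = highest frequency)
  if (!is.unsorted(img$freq_axis)) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  rgb <- apply_jet(v)
  out <- array(0, c(size, size, 3L))
  for (c in 1:3) out[, , c] <- resize_bilinear(rgb[, , c], size, size)
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(path)) {
    ok <- tryCatch({ png::writePNG(out, target = path); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop(sprintf("failed to write PNG to '%s'", path), call. = FALSE)
    return(invisible(out))
  }
  out
}

#' File name for a rendered time-frequency image
#'
#' Encodes subject, epoch index, channel and representation as
#' `<subject>_<epoch>_<channel>_<repr>.png`; [parse_tf_filename()] inverts it.
#'
#' @param img A [tf_image()] with complete metadata.
#' @return File name string.
#' @export
tf_filename <- function(img) {
  stopifnot(inherits(img, "tf_image"))
  sprintf("%s_%d_%s_%s.png", img$subject_id, img$epoch_index,
          img$channel_label, img$repr)
}

#' Parse image metadata back out of a file name
#'
#' @param fname File name produced by [tf_filename()].
#' @return List with `subject_id`, `epoch_index`, `channel_label`, `repr`.
#' @export
parse_tf_filename <- function(fname) {
  base <- sub("\\.png$", "", basename(fname))
  parts <- strsplit(base, "_", fixed = TRUE)[[1L]]
  if (length(parts) < 4L) stop("not a recognised time-frequency image file name",
                               call. = FALSE)
  n <- length(parts)
  list(subject_id = paste(parts[seq_len(n - 3L)], collapse = "_"),
       epoch_index = as.integer(parts[n - 2L]),
       channel_label = parts[n - 1L],
       repr = parts[n])
}
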