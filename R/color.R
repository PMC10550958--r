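# Color (PET/SPECT) pathway: fuse the functional image's luminance with
# the MRI through the grayscale pipeline, keep chrominance untouched.
# "YUV" is analog BT.601: Y = 0.299 R + 0.587 G + 0.114 B,
# U = 0.492 (B - Y), V = 0.877 (R - Y), computed in floating point on the
# 0-255 scale; chrominance stays signed and unquantized between the two
# transforms so the round trip is exact.

#' RGB to YUV (BT.601)
#'
#' @param img `A x B x 3` RGB array on the `[0, 255]` scale.
#' @return A list with class `"yuv_image"`: `y` in `[0, 255]`, signed
#'   `u`, `v` matrices.
#' @export
rgb_to_yuv <- function(img) {
  check_color_image(img)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  structure(list(y = y, u = 0.492 * (b - y), v = 0.877 * (r - y)),
            class = "yuv_image")
}

#' YUV (BT.601) to RGB
#'
#' Exact matrix inverse of [rgb_to_yuv()], followed by clipping to
#' `[0, 255]` (out-of-gamut values can arise when the luminance plane was
#' replaced by a fused one).
#'
#' @param img A `yuv_image` (list with `y`, `u`, `v` matrices).
#' @return `A x B x 3` RGB array in `[0, 255]`.
#' @export
yuv_to_rgb <- function(img) {
  stopifnot(is.list(img), all(c("y", "u", "v") %in% names(img)))
  y <- img$y; u <- img$u; v <- img$v
  if (!identical(dim(y), dim(u)) || !identical(dim(y), dim(v))) {
    stop("YUV planes must share dimensions", call. = FALSE)
  }
  r <- y + v / 0.877
  b <- y + u / 0.492
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(0, c(dim(y), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  pmin(pmax(out, 0), 255)
}

#' Fuse an MRI with a color functional image (PET/SPECT)
#'
#' The functional image is converted to YUV; its luminance plane is fused
#' with the MRI through [fuse_gray()]; the fused luminance is recombined
#' with the *unchanged* chrominance planes and converted back to RGB.
#'
#' @param mri Grayscale matrix.
#' @param functional `A x B x 3` RGB array of the same height/width.
#' @param config A [fusion_config()].
#' @return A list: `fused` (RGB array) and `result` (the grayscale
#'   `pfs_fusion` object for the luminance fusion).
#' @examples
#' pair <- make_pair("mri_pet", size = 64, seed = 2)
#' out <- fuse_color(pair[[1]], pair[[2]])
#' dim(out$fused)
#' @export
fuse_color <- function(mri, functional, config = fusion_config()) {
  check_gray_image(mri)
  check_color_image(functional)
  if (!identical(dim(mri), dim(functional)[1:2])) {
    stop(sprintf("input dimensions differ: %dx%d vs %dx%d",
                 nrow(mri), ncol(mri), dim(functional)[1], dim(functional)[2]),
         call. = FALSE)
  }
  yuv <- rgb_to_yuv(functional)
  result <- fuse_gray(mri, yuv$y, config)
  fused <- yuv_to_rgb(list(y = result$fused, u = yuv$u, v = yuv$v))
  list(fused = fused, result = result)
}
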