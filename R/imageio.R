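#' Validate a grayscale image matrix
#'
#' Grayscale images are plain numeric matrices on the display scale
#' (nominally `[0, 255]`), `A` rows (height) by `B` columns (width).
#' Several operations take first differences, so both dimensions must be
#' at least 2.
#'
#' @param x Object to validate.
#' @param arg Name used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @keywords internal
check_gray_image <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop(sprintf("`%s` must be at least 2x2 (got %dx%d)", arg, nrow(x), ncol(x)),
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(x)
}

check_color_image <- function(x, arg = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L || !is.numeric(x)) {
    stop(sprintf("`%s` must be an A x B x 3 numeric array", arg), call. = FALSE)
  }
  if (dim(x)[1] < 2L || dim(x)[2] < 2L) {
    stop(sprintf("`%s` must be at least 2x2", arg), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  }
  invisible(x)
}

.image_ext <- function(path) tolower(tools::file_ext(path))

#' Read a raster image
#'
#' Reads an 8- or 16-bit PNG, TIFF, or JPEG file. Single-channel files
#' yield a grayscale matrix; three-channel files yield an `A x B x 3`
#' array (an RGB image whose channels happen to be equal is *not*
#' collapsed to grayscale). Values are returned on the `[0, 255]` display
#' scale: 16-bit inputs are linearly rescaled, and any alpha channel is
#' dropped.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return A numeric matrix (grayscale) or an `A x B x 3` numeric array (RGB).
#' @examples
#' p <- tempfile(fileext = ".png")
#' write_image(make_phantom("checkerboard", size = 32), p)
#' img <- read_image(p)
#' dim(img)
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path, call. = FALSE)
  ext <- .image_ext(path)
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  # readers return values on [0, 1] regardless of source bit depth
  raw <- raw * 255
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3]
    if (nc == 2L) raw <- raw[, , 1L]            # gray + alpha
    else if (nc >= 4L) raw <- raw[, , 1:3]      # drop alpha
    else if (nc == 1L) raw <- raw[, , 1L]
  }
  if (length(dim(raw)) == 3L) check_color_image(raw, "image") else {
    raw <- as.matrix(raw)
    check_gray_image(raw, "image")
  }
  raw
}

#' Write a raster image
#'
#' Values are clipped to `[0, 255]`, rounded half-up to integers, and
#' written as 8-bit PNG or TIFF according to the file extension.
#'
#' @param image Grayscale matrix or `A x B x 3` RGB array on the
#'   `[0, 255]` scale.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (length(dim(image)) == 3L) check_color_image(image) else check_gray_image(image)
  q <- floor(pmin(pmax(image, 0), 255) + 0.5) / 255
  ext <- .image_ext(path)
  switch(ext,
    png  = png::writePNG(q, path),
    tif  = ,
    tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
    stop("unsupported output format: .", ext, call. = FALSE)
  )
  invisible(path)
}
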