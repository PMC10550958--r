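# The seven objective fusion-quality measures. All gradient-style
# metrics operate on the unquantized image; only mutual information
# quantizes (256 equal bins over [0, 255], log base 2).

#' Mean intensity of an image
#' @param u Grayscale matrix.
#' @return Arithmetic mean of all pixels.
#' @export
mean_metric <- function(u) {
  check_gray_image(u)
  mean(u)
}

#' Population standard deviation of an image
#'
#' Divides by the full pixel count `A * B`, not `A * B - 1`.
#'
#' @param u Grayscale matrix.
#' @return Nonnegative scalar.
#' @export
sd_metric <- function(u) {
  check_gray_image(u)
  sqrt(mean((u - mean(u))^2))
}

#' Average gradient of an image
#'
#' Mean over the `(A-1) x (B-1)` interior grid of
#' `sqrt((d_a^2 + d_b^2) / 2)` with forward differences along rows and
#' columns.
#'
#' @param u Grayscale matrix, at least 2 x 2.
#' @return Nonnegative scalar.
#' @export
avg_gradient <- function(u) {
  check_gray_image(u)
  a <- nrow(u); b <- ncol(u)
  da <- u[-a, -b, drop = FALSE] - u[-1L, -b, drop = FALSE]
  db <- u[-a, -b, drop = FALSE] - u[-a, -1L, drop = FALSE]
  mean(sqrt((da^2 + db^2) / 2))
}

#' Spatial frequency of an image
#'
#' `sqrt(RF^2 + CF^2)` with row and column difference energies both
#' normalized by the full pixel count `A * B`.
#'
#' @param u Grayscale matrix, at least 2 x 2.
#' @return Nonnegative scalar.
#' @export
sf_metric <- function(u) {
  check_gray_image(u)
  n <- length(u)
  rf2 <- sum((u[, -1L, drop = FALSE] - u[, -ncol(u), drop = FALSE])^2) / n
  cf2 <- sum((u[-1L, , drop = FALSE] - u[-nrow(u), , drop = FALSE])^2) / n
  sqrt(rf2 + cf2)
}

#' Modified spatial frequency of an image
#'
#' Adds a diagonal term to the spatial frequency:
#' `sqrt(RF^2 + CF^2 + DF^2)`, where RF is normalized by `A (B - 1)`, CF
#' by `(A - 1) B`, and DF is the *sum* of the two diagonal RMS terms
#' (main and anti-diagonal first differences, each normalized by
#' `(A - 1)(B - 1)`). The normalizers deliberately differ from
#' [sf_metric()]'s; both definitions are kept as printed in the fusion
#' literature rather than harmonized, so `msf >= sf` for every image.
#'
#' @param u Grayscale matrix, at least 2 x 2.
#' @return Nonnegative scalar.
#' @export
msf_metric <- function(u) {
  check_gray_image(u)
  a <- nrow(u); b <- ncol(u)
  rf2 <- sum((u[, -1L, drop = FALSE] - u[, -b, drop = FALSE])^2) / (a * (b - 1))
  cf2 <- sum((u[-1L, , drop = FALSE] - u[-a, , drop = FALSE])^2) / ((a - 1) * b)
  dmain <- u[-1L, -1L, drop = FALSE] - u[-a, -b, drop = FALSE]
  danti <- u[-a, -1L, drop = FALSE] - u[-1L, -b, drop = FALSE]
  au <- sqrt(sum(dmain^2) / ((a - 1) * (b - 1)))
  bu <- sqrt(sum(danti^2) / ((a - 1) * (b - 1)))
  sqrt(rf2 + cf2 + (au + bu)^2)
}

.quantize <- function(u, bins) {
  as.integer(round(pmin(pmax(u, 0), 255) / 255 * (bins - 1L)))
}

#' Mutual information between two images
#'
#' Computed from the joint histogram of intensities quantized to `bins`
#' equal bins over `[0, 255]` (nearest-bin rounding), in bits (log base
#' 2); empty cells contribute zero.
#'
#' @param u,x Same-size grayscale matrices.
#' @param bins Number of histogram bins, `>= 2` (default 256).
#' @return Nonnegative scalar (bits).
#' @export
mutual_information <- function(u, x, bins = 256L) {
  check_gray_image(u)
  check_gray_image(x)
  if (!identical(dim(u), dim(x))) stop("images must share dimensions", call. = FALSE)
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  bins <- as.integer(bins)
  qu <- .quantize(u, bins)
  qx <- .quantize(x, bins)
  joint <- tabulate(qu * bins + qx + 1L, nbins = bins * bins) / length(u)
  jm <- matrix(joint, bins, bins, byrow = TRUE)  # rows: u bins, cols: x bins
  pu <- rowSums(jm)
  px <- colSums(jm)
  nz <- which(jm > 0, arr.ind = TRUE)
  p <- jm[nz]
  sum(p * log2(p / (pu[nz[, 1]] * px[nz[, 2]])))
}

#' Fusion symmetry of a fused image with respect to its sources
#'
#' `fs = 2 - |MI(U, X1) / MI_T - 0.5|` with
#' `MI_T = MI(U, X1) + MI(U, X2)`; always in `[1.5, 2]`, and exactly 2
#' when both sources contribute equal information. When `MI_T == 0` the
#' ratio is undefined and `fs` is reported as `NA`.
#'
#' @param u Fused grayscale matrix.
#' @param x1,x2 Source grayscale matrices, same size as `u`.
#' @param bins Histogram bins for the underlying mutual information.
#' @return A list: `fs`, `mi_t`, `mi_ux1`, `mi_ux2`.
#' @export
fusion_symmetry <- function(u, x1, x2, bins = 256L) {
  mi1 <- mutual_information(u, x1, bins)
  mi2 <- mutual_information(u, x2, bins)
  mi_t <- mi1 + mi2
  fs <- if (mi_t > 0) 2 - abs(mi1 / mi_t - 0.5) else NA_real_
  list(fs = fs, mi_t = mi_t, mi_ux1 = mi1, mi_ux2 = mi2)
}

#' All seven fusion-quality metrics as a one-row tibble
#'
#' Columns follow the conventional report order: mean, standard
#' deviation, average gradient, spatial frequency, modified spatial
#' frequency, total mutual information, fusion symmetry, plus the two
#' per-source mutual informations.
#'
#' @param u Fused grayscale matrix.
#' @param x1,x2 Source grayscale matrices.
#' @param bins Histogram bins for mutual information (default 256).
#' @return A one-row tibble with columns `m`, `sd`, `ag`, `sf`, `msf`,
#'   `mi`, `fs`, `mi_ux1`, `mi_ux2`.
#' @export
fusion_metrics <- function(u, x1, x2, bins = 256L) {
  fsym <- fusion_symmetry(u, x1, x2, bins)
  tibble::tibble(
    m = mean_metric(u), sd = sd_metric(u), ag = avg_gradient(u),
    sf = sf_metric(u), msf = msf_metric(u),
    mi = fsym$mi_t, fs = fsym$fs,
    mi_ux1 = fsym$mi_ux1, mi_ux2 = fsym$mi_ux2
  )
}
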