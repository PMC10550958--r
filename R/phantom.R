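# Deterministic geometric phantoms standing in for clinical image pairs:
# a bone-like ring image (CT-like), a soft-tissue blob image (MRI-like),
# a vessel-like image (MRA-like), and a pseudo-colored hotspot image
# (PET/SPECT-like). All randomness is locally seeded; identical specs
# give bitwise-identical images. These are synthetic stand-ins, not
# samples of real anatomy.

.phantom_kinds <- c("ct_like", "mri_like", "pet_like", "checkerboard",
                    "ramp", "constant", "noise", "mra_like")

.norm_coords <- function(a, b) {
  yg <- matrix(seq(-1, 1, length.out = a), a, b)
  xg <- matrix(seq(-1, 1, length.out = b), a, b, byrow = TRUE)
  list(x = xg, y = yg)
}

.gauss_blob <- function(co, cx, cy, sx, sy) {
  exp(-((co$x - cx)^2 / (2 * sx^2) + (co$y - cy)^2 / (2 * sy^2)))
}

# hot colormap: black -> red -> yellow -> white on t in [0, 1]
.hot_rgb <- function(t) {
  r <- pmin(1, 3 * t)
  g <- pmin(1, pmax(0, 3 * t - 1))
  b <- pmin(1, pmax(0, 3 * t - 2))
  out <- array(0, c(dim(t), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out * 255
}

.phantom_gray <- function(kind, a, b, value, noise_sd) {
  co <- .norm_coords(a, b)
  r <- sqrt((co$x / 0.85)^2 + (co$y / 0.95)^2)
  img <- switch(kind,
    ct_like = {
      m <- matrix(10, a, b)
      m[r <= 1] <- 40
      m[r <= 1 & r > 0.82] <- 235            # dense skull-like ring
      # bright dense inner structures (falx / calcification stand-ins)
      m <- m + 190 * (abs(co$x) < 0.03 & abs(co$y) < 0.55) * (r <= 0.8)
      m + 160 * .gauss_blob(co, 0.35, 0.3, 0.06, 0.1) * (r <= 0.8)
    },
    mri_like = {
      m <- matrix(5, a, b)
      m[r <= 1] <- 120                       # soft-tissue interior
      m[r <= 1 & r > 0.82] <- 60             # skull is dim on MR
      inner <- r <= 0.8
      m <- m + inner * (70 * .gauss_blob(co, -0.3, -0.2, 0.2, 0.25) -
                          60 * .gauss_blob(co, 0.25, 0.15, 0.15, 0.2) +
                          50 * .gauss_blob(co, 0.1, -0.45, 0.12, 0.1))
      # ventricle-like dark slots
      m - inner * 80 * .gauss_blob(co, 0, 0.05, 0.05, 0.3)
    },
    mra_like = {
      m <- matrix(15, a, b)
      m[r <= 1] <- 30
      vessel1 <- abs(co$y - 0.5 * sin(3 * co$x)) < 0.035
      vessel2 <- abs(co$x + 0.4 * sin(2.5 * co$y + 1)) < 0.03
      m[(vessel1 | vessel2) & r <= 0.9] <- 235
      m
    },
    checkerboard = {
      tiles <- (floor((row(matrix(0, a, b)) - 1) / 8) +
                  floor((col(matrix(0, a, b)) - 1) / 8)) %% 2
      tiles * 255
    },
    ramp = matrix(seq(0, 255, length.out = b), a, b, byrow = TRUE),
    constant = matrix(value, a, b),
    noise = matrix(rnorm(a * b, mean = 128,
                         sd = if (noise_sd > 0) noise_sd else 40), a, b)
  )
  if (noise_sd > 0 && kind != "noise") img <- img + rnorm(a * b, sd = noise_sd)
  pmin(pmax(img, 0), 255)
}

#' Generate a deterministic phantom image
#'
#' @param kind One of `"ct_like"`, `"mri_like"`, `"mra_like"`,
#'   `"pet_like"`, `"checkerboard"`, `"ramp"`, `"constant"`, `"noise"`.
#'   `pet_like` yields an `A x B x 3` pseudo-colored (hot colormap)
#'   hotspot image; all other kinds yield grayscale matrices.
#' @param size Image size: scalar (square) or `c(A, B)`. Structured kinds
#'   require at least 16 x 16.
#' @param seed Integer seed; the same spec always yields bitwise
#'   identical pixels. Global random state is left untouched.
#' @param noise_sd Additive Gaussian noise standard deviation in gray
#'   levels (and the field SD for `kind = "noise"`, default 40 there).
#' @param value Constant gray level for `kind = "constant"`.
#' @return Grayscale matrix or RGB array with values in `[0, 255]`.
#' @examples
#' ct <- make_phantom("ct_like", size = 64, seed = 1)
#' range(ct)
#' @export
make_phantom <- function(kind, size = c(256L, 256L), seed = 1L,
                         noise_sd = 0, value = 100) {
  kind <- match.arg(kind, .phantom_kinds)
  if (length(size) == 1L) size <- c(size, size)
  a <- as.integer(size[1]); b <- as.integer(size[2])
  structured <- !(kind %in% c("constant", "ramp", "noise", "checkerboard"))
  if (structured && (a < 16L || b < 16L)) {
    stop("structured phantoms require size >= 16x16", call. = FALSE)
  }
  if (a < 2L || b < 2L) stop("phantom size must be at least 2x2", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    if (kind == "pet_like") {
      co <- .norm_coords(a, b)
      r <- sqrt((co$x / 0.85)^2 + (co$y / 0.95)^2)
      centers <- cbind(runif(3, -0.5, 0.5), runif(3, -0.5, 0.5))
      field <- 0.9 * .gauss_blob(co, centers[1, 1], centers[1, 2], 0.18, 0.18) +
        0.7 * .gauss_blob(co, centers[2, 1], centers[2, 2], 0.25, 0.2) +
        0.5 * .gauss_blob(co, centers[3, 1], centers[3, 2], 0.12, 0.15)
      field <- field / max(field) * (r <= 1)
      if (noise_sd > 0) {
        field <- pmin(pmax(field + rnorm(a * b, sd = noise_sd / 255), 0), 1)
      }
      .hot_rgb(field)
    } else {
      .phantom_gray(kind, a, b, value, noise_sd)
    }
  })
}

#' Generate a registered multimodal phantom pair
#'
#' Emulates the modality pairings used in multimodal fusion studies.
#' Grayscale kinds return two matrices; `mri_pet` and `mri_spect` return
#' a grayscale MRI-like image and an RGB pseudo-colored functional image.
#'
#' @param kind One of `"mr_t1_t2"`, `"mri_ct"`, `"mr_mra"`, `"mri_pet"`,
#'   `"mri_spect"`.
#' @param size Image size (scalar or `c(A, B)`).
#' @param seed Integer seed.
#' @param noise_sd Additive noise SD in gray levels.
#' @return A named list of two images, `x1` and `x2`.
#' @export
make_pair <- function(kind, size = c(256L, 256L), seed = 1L, noise_sd = 0) {
  kind <- match.arg(kind, c("mr_t1_t2", "mri_ct", "mr_mra", "mri_pet", "mri_spect"))
  seed <- as.integer(seed)
  switch(kind,
    mr_t1_t2 = list(
      x1 = make_phantom("mri_like", size, seed, noise_sd),
      # T2-like contrast: bright fluid where T1 is dark
      x2 = {
        m <- make_phantom("mri_like", size, seed + 1L, noise_sd)
        pmin(pmax(200 - 0.7 * m, 0), 255)
      }
    ),
    mri_ct = list(
      x1 = make_phantom("mri_like", size, seed, noise_sd),
      x2 = make_phantom("ct_like", size, seed + 1L, noise_sd)
    ),
    mr_mra = list(
      x1 = make_phantom("mri_like", size, seed, noise_sd),
      x2 = make_phantom("mra_like", size, seed + 1L, noise_sd)
    ),
    mri_pet = list(
      x1 = make_phantom("mri_like", size, seed, noise_sd),
      x2 = make_phantom("pet_like", size, seed + 1L, noise_sd)
    ),
    mri_spect = list(
      x1 = make_phantom("mri_like", size, seed, noise_sd),
      x2 = make_phantom("pet_like", size, seed + 7L, noise_sd)
    )
  )
}
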