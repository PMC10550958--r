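# Block-based fusion rules and the grayscale pipeline. Planes that do not
# divide evenly into blocks are padded by edge replication and cropped
# after reassembly, so output shape always equals input shape.

.pad_to_blocks <- function(m, block_h, block_w) {
  a <- nrow(m); b <- ncol(m)
  ap <- ceiling(a / block_h) * block_h
  bp <- ceiling(b / block_w) * block_w
  m[c(seq_len(a), rep(a, ap - a)), c(seq_len(b), rep(b, bp - b)), drop = FALSE]
}

#' Partition a plane into equal blocks
#'
#' Pads the plane by edge replication up to the next multiples of the
#' block dimensions and returns the half-open index windows that tile the
#' padded plane exactly.
#'
#' @param plane Numeric matrix.
#' @param block_h,block_w Positive block dimensions.
#' @return A list with class `"block_grid"`: `block_h`, `block_w`,
#'   `padded_dim`, and `blocks`, a list of `list(rows =, cols =)` integer
#'   index vectors.
#' @export
partition_blocks <- function(plane, block_h, block_w) {
  if (block_h < 1 || block_w < 1) stop("block dimensions must be >= 1", call. = FALSE)
  block_h <- as.integer(block_h); block_w <- as.integer(block_w)
  ap <- as.integer(ceiling(nrow(plane) / block_h) * block_h)
  bp <- as.integer(ceiling(ncol(plane) / block_w) * block_w)
  rows <- seq(1L, ap, by = block_h)
  cols <- seq(1L, bp, by = block_w)
  blocks <- vector("list", length(rows) * length(cols))
  k <- 1L
  for (r in rows) for (cc in cols) {
    blocks[[k]] <- list(rows = r:(r + block_h - 1L), cols = cc:(cc + block_w - 1L))
    k <- k + 1L
  }
  structure(list(block_h = block_h, block_w = block_w,
                 padded_dim = c(ap, bp), blocks = blocks),
            class = "block_grid")
}

#' Blackness and whiteness counts of a block pair
#'
#' Pooled over both blocks: blackness is the number of entries strictly
#' below 0.5, whiteness the number strictly above; entries equal to 0.5
#' count toward neither.
#'
#' @param block1,block2 Same-shape numeric blocks with values in `[0, 1]`.
#' @return Integer vector `c(blackness =, whiteness =)`.
#' @export
black_white_counts <- function(block1, block2) {
  if (!identical(dim(block1), dim(block2))) {
    stop("blocks must share dimensions", call. = FALSE)
  }
  v <- c(block1, block2)
  c(blackness = sum(v < 0.5), whiteness = sum(v > 0.5))
}

# iterate a two-plane block rule over a shared grid, then crop padding
.block_apply2 <- function(p1, p2, block_h, block_w, rule) {
  a <- nrow(p1); b <- ncol(p1)
  q1 <- .pad_to_blocks(p1, block_h, block_w)
  q2 <- .pad_to_blocks(p2, block_h, block_w)
  grid <- partition_blocks(p1, block_h, block_w)
  out <- matrix(0, nrow(q1), ncol(q1))
  for (w in grid$blocks) {
    out[w$rows, w$cols] <- rule(q1[w$rows, w$cols, drop = FALSE],
                                q2[w$rows, w$cols, drop = FALSE])
  }
  out[seq_len(a), seq_len(b), drop = FALSE]
}

#' Base-layer block fusion by blackness/whiteness counts
#'
#' Per block: where pooled blackness exceeds whiteness the elementwise
#' minimum of the two blocks is taken (dark content dominates), where
#' whiteness exceeds blackness the maximum, and the average on ties.
#'
#' @param plane1,plane2 Same-shape membership planes (`membership_plane`
#'   objects or plain matrices in `[0, 1]`).
#' @param block_h,block_w Block dimensions (default 8 x 8).
#' @return Fused matrix in `[0, 1]`, same shape as the inputs.
#' @export
fuse_base <- function(plane1, plane2, block_h = 8L, block_w = 8L) {
  if (inherits(plane1, "membership_plane")) plane1 <- plane1$mu
  if (inherits(plane2, "membership_plane")) plane2 <- plane2$mu
  if (!identical(dim(plane1), dim(plane2))) {
    stop("planes must share dimensions", call. = FALSE)
  }
  .block_apply2(plane1, plane2, block_h, block_w, function(b1, b2) {
    cnt <- black_white_counts(b1, b2)
    if (cnt[["blackness"]] > cnt[["whiteness"]]) pmin(b1, b2)
    else if (cnt[["blackness"]] < cnt[["whiteness"]]) pmax(b1, b2)
    else (b1 + b2) / 2
  })
}

#' Spatial frequency of a block
#'
#' RMS activity of horizontal (row) and vertical (column) first
#' differences, both normalized by the full block pixel count:
#' `SF = sqrt(RF^2 + CF^2)`. Invariant to adding a constant.
#'
#' @param block Numeric matrix, at least 2 x 2.
#' @return Nonnegative scalar.
#' @export
block_sf <- function(block) {
  if (nrow(block) < 2L || ncol(block) < 2L) {
    stop("`block` must be at least 2x2", call. = FALSE)
  }
  n <- length(block)
  rf2 <- sum((block[, -1L, drop = FALSE] - block[, -ncol(block), drop = FALSE])^2) / n
  cf2 <- sum((block[-1L, , drop = FALSE] - block[-nrow(block), , drop = FALSE])^2) / n
  sqrt(rf2 + cf2)
}

#' Detail-layer block fusion by spatial frequency
#'
#' Per block: the block with the clearly higher spatial frequency is
#' copied through (higher by more than the margin `th`); when neither
#' dominates, the blocks are averaged.
#'
#' @param detail1,detail2 Same-shape signed detail matrices.
#' @param block_h,block_w Block dimensions (default 8 x 8).
#' @param th Nonnegative decision margin (default 0).
#' @return Fused detail matrix, same shape as the inputs.
#' @export
fuse_detail <- function(detail1, detail2, block_h = 8L, block_w = 8L, th = 0) {
  if (!identical(dim(detail1), dim(detail2))) {
    stop("detail layers must share dimensions", call. = FALSE)
  }
  if (th < 0) stop("`th` must be >= 0", call. = FALSE)
  .block_apply2(detail1, detail2, block_h, block_w, function(b1, b2) {
    s1 <- block_sf(b1); s2 <- block_sf(b2)
    if (s1 > s2 + th) b1
    else if (s2 > s1 + th) b2
    else (b1 + b2) / 2
  })
}

#' Fuse two pre-registered grayscale images
#'
#' The full pipeline: both images are split into Gaussian base and
#' residual detail layers; each base layer is min-max fuzzified and its
#' fuzzification parameter selected by Pythagorean-fuzzy-entropy
#' maximization; the membership planes (hedge + INT enhanced when
#' `config$enhance` is `TRUE`, raw otherwise) are fused block-wise by the
#' blackness/whiteness rule and defuzzified over the pooled gray-level
#' range of both base layers; detail layers are fused block-wise by
#' spatial frequency; the fused image is the sum of the two fused layers,
#' kept unclipped (clipping to `[0, 255]` happens only in
#' [write_image()]).
#'
#' @param x1,x2 Same-size grayscale matrices on the `[0, 255]` scale.
#' @param config A [fusion_config()].
#' @return An object of class `"pfs_fusion"`: `fused`, `base_fused`,
#'   `detail_fused`, `alpha` (per-source optima), `pfe_curves` (list of
#'   tibbles), `anchors`, `metrics` (tibble, see [fusion_metrics()]) and
#'   `config`.
#' @examples
#' pair <- make_pair("mri_ct", size = 64, seed = 1)
#' res <- fuse_gray(pair[[1]], pair[[2]])
#' res$alpha
#' res$metrics
#' @export
fuse_gray <- function(x1, x2, config = fusion_config()) {
  check_gray_image(x1)
  check_gray_image(x2)
  if (!identical(dim(x1), dim(x2))) {
    stop(sprintf("input dimensions differ: %dx%d vs %dx%d",
                 nrow(x1), ncol(x1), nrow(x2), ncol(x2)), call. = FALSE)
  }
  stopifnot(inherits(config, "fusion_config"))

  d1 <- decompose_image(x1, config$sigma, config$kernel_size)
  d2 <- decompose_image(x2, config$sigma, config$kernel_size)

  f1 <- fuzzify(d1$base)
  f2 <- fuzzify(d2$base)
  grid <- alpha_grid(config)
  o1 <- optimize_alpha(f1, grid)
  o2 <- optimize_alpha(f2, grid)
  pfi1 <- build_pfi(f1, o1$alpha_opt)
  pfi2 <- build_pfi(f2, o2$alpha_opt)

  # With enhancement on, the contrast-modified PFS memberships carry the
  # geometry into the block rule; with enhancement off the raw membership
  # planes do, so defuzzification is the exact inverse of fuzzification
  # and fusing an image with itself reproduces it.
  if (config$enhance) {
    p1 <- enhance(pfi1, config$lambda)$mu
    p2 <- enhance(pfi2, config$lambda)$mu
  } else {
    p1 <- f1$mu
    p2 <- f2$mu
  }

  fused_plane <- fuse_base(p1, p2, config$block_h, config$block_w)
  y_min <- min(f1$y_min, f2$y_min)
  y_max <- max(f1$y_max, f2$y_max)
  base_fused <- defuzzify(fused_plane, y_min, y_max)

  detail_fused <- fuse_detail(d1$detail, d2$detail,
                              config$block_h, config$block_w, config$th)
  fused <- reconstruct_image(base_fused, detail_fused)

  structure(
    list(fused = fused, base_fused = base_fused, detail_fused = detail_fused,
         alpha = c(o1$alpha_opt, o2$alpha_opt),
         pfe_curves = list(o1$curve, o2$curve),
         anchors = c(y_min = y_min, y_max = y_max),
         metrics = fusion_metrics(fused, x1, x2),
         config = config),
    class = "pfs_fusion"
  )
}

#' @export
print.pfs_fusion <- function(x, ...) {
  cat(sprintf("Pythagorean fuzzy image fusion (%d x %d)\n",
              nrow(x$fused), ncol(x$fused)))
  cat(sprintf("  alpha_opt: %.2f (source 1), %.2f (source 2)\n",
              x$alpha[1], x$alpha[2]))
  cat(sprintf("  base anchors: [%.2f, %.2f]; enhancement %s\n",
              x$anchors[["y_min"]], x$anchors[["y_max"]],
              if (x$config$enhance) "on" else "off"))
  cat("  metrics:\n")
  print(x$metrics)
  invisible(x)
}
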