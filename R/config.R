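#' Fusion pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with validated
#' defaults: Gaussian smoothing scale, block size for both block-fusion
#' rules, the spatial-frequency decision margin `th`, the hedge exponent,
#' the alpha search grid, and the enhancement switch.
#'
#' @param sigma Gaussian standard deviation in pixels (default 5).
#' @param kernel_size Odd kernel size; `NULL` derives `2*ceiling(3*sigma)+1`.
#' @param block_h,block_w Block dimensions for base and detail fusion
#'   (default 8 x 8).
#' @param th Nonnegative spatial-frequency margin: a detail block is taken
#'   from one source only when its SF exceeds the other's by more than
#'   `th`; otherwise blocks are averaged (default 0).
#' @param lambda Fuzzy hedge exponent, `>= 1` (default 2).
#' @param alpha_start,alpha_stop,alpha_step Search grid for the
#'   fuzzification parameter (default 0.01 to 1 in steps of 0.01).
#' @param enhance Logical; apply hedge + INT enhancement to the PFS
#'   membership planes before base fusion (default `TRUE`). When
#'   `FALSE` the raw membership planes are fused, which makes fusing an
#'   image with itself an exact identity.
#' @return A list with class `"fusion_config"`.
#' @examples
#' cfg <- fusion_config(sigma = 3, block_h = 4, block_w = 4, enhance = FALSE)
#' @export
fusion_config <- function(sigma = 5, kernel_size = NULL,
                          block_h = 8L, block_w = 8L, th = 0,
                          lambda = 2,
                          alpha_start = 0.01, alpha_stop = 1, alpha_step = 0.01,
                          enhance = TRUE) {
  chk <- function(ok, key, what) {
    if (!ok) stop(sprintf("invalid config value for `%s`: %s", key, what),
                  call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(sigma) && sigma > 0, "gaussian.sigma", "must be > 0")
  if (!is.null(kernel_size)) {
    chk(num1(kernel_size) && kernel_size >= 3 && kernel_size %% 2 == 1,
        "gaussian.kernel_size", "must be an odd integer >= 3")
    kernel_size <- as.integer(kernel_size)
  }
  chk(num1(block_h) && block_h >= 1, "block.h", "must be a positive integer")
  chk(num1(block_w) && block_w >= 1, "block.w", "must be a positive integer")
  chk(num1(th) && th >= 0, "detail.th", "must be >= 0")
  chk(num1(lambda) && lambda >= 1, "enhance.lambda", "must be >= 1")
  chk(num1(alpha_start) && alpha_start > 0, "alpha.start", "must be > 0")
  chk(num1(alpha_stop) && alpha_stop <= 1 && alpha_stop >= alpha_start,
      "alpha.stop", "must be in [alpha.start, 1]")
  chk(num1(alpha_step) && alpha_step > 0, "alpha.step", "must be > 0")
  chk(isTRUE(enhance) || isFALSE(enhance), "enhance.enabled", "must be TRUE/FALSE")
  structure(
    list(sigma = sigma, kernel_size = kernel_size,
         block_h = as.integer(block_h), block_w = as.integer(block_w),
         th = th, lambda = lambda,
         alpha_start = alpha_start, alpha_stop = alpha_stop,
         alpha_step = alpha_step, enhance = enhance),
    class = "fusion_config"
  )
}

alpha_grid <- function(config) {
  seq(config$alpha_start, config$alpha_stop, by = config$alpha_step)
}

#' Load a fusion configuration from YAML and overrides
#'
#' Precedence is defaults, then the YAML file, then `overrides`
#' (typically command-line flags). The YAML layout mirrors the config
#' keys: `gaussian: {sigma, kernel_size}`, `block: {h, w}`,
#' `detail: {th}`, `enhance: {lambda, enabled}`,
#' `alpha: {start, stop, step}`.
#'
#' @param path Optional path to a YAML file.
#' @param overrides Named list of [fusion_config()] arguments that win
#'   over both defaults and file values.
#' @return A validated `fusion_config`.
#' @export
load_fusion_config <- function(path = NULL, overrides = list()) {
  args <- list()
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    pick <- function(...) {
      v <- y
      for (k in c(...)) {
        if (is.null(v)) return(NULL)
        v <- v[[k]]
      }
      v
    }
    file_args <- list(
      sigma = pick("gaussian", "sigma"),
      kernel_size = pick("gaussian", "kernel_size"),
      block_h = pick("block", "h"),
      block_w = pick("block", "w"),
      th = pick("detail", "th"),
      lambda = pick("enhance", "lambda"),
      enhance = pick("enhance", "enabled"),
      alpha_start = pick("alpha", "start"),
      alpha_stop = pick("alpha", "stop"),
      alpha_step = pick("alpha", "step")
    )
    args <- file_args[!vapply(file_args, is.null, logical(1))]
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  args[names(overrides)] <- overrides
  do.call(fusion_config, args)
}
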