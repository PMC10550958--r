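# Pythagorean fuzzy machinery: min-max fuzzification, the alpha-negation,
# PFS membership/non-membership/indeterminacy planes, Pythagorean fuzzy
# entropy and its maximization over alpha, hedge + INT enhancement, and
# defuzzification.

#' Fuzzify a grayscale image by min-max normalization
#'
#' Maps gray levels linearly onto `[0, 1]` using the image's own minimum
#' and maximum, which are stored as anchors so the mapping can be
#' inverted by [defuzzify()]. A constant image (max equals min) is mapped
#' to the maximally ambiguous plane `mu == 0.5`, with both anchors equal
#' to the constant so the round trip still recovers it.
#'
#' @param image Grayscale matrix.
#' @return A list with class `"membership_plane"`: `mu` (matrix in
#'   `[0, 1]`), `y_min`, `y_max`.
#' @export
fuzzify <- function(image) {
  check_gray_image(image)
  y_min <- min(image)
  y_max <- max(image)
  mu <- if (y_max > y_min) (image - y_min) / (y_max - y_min) else
    matrix(0.5, nrow(image), ncol(image))
  structure(list(mu = mu, y_min = y_min, y_max = y_max),
            class = "membership_plane")
}

#' Map a membership plane back to gray levels
#'
#' Inverse of the min-max fuzzification: `(y_max - y_min) * value + y_min`
#' elementwise, so the output range is contained in `[y_min, y_max]`.
#'
#' @param plane A `membership_plane` or a plain matrix in `[0, 1]`.
#' @param y_min,y_max Gray-level anchors; default to the plane's own.
#' @return Grayscale matrix.
#' @export
defuzzify <- function(plane, y_min = NULL, y_max = NULL) {
  if (inherits(plane, "membership_plane")) {
    if (is.null(y_min)) y_min <- plane$y_min
    if (is.null(y_max)) y_max <- plane$y_max
    plane <- plane$mu
  }
  if (is.null(y_min) || is.null(y_max)) {
    stop("`y_min` and `y_max` are required for a bare matrix", call. = FALSE)
  }
  if (y_min > y_max) stop("`y_min` must not exceed `y_max`", call. = FALSE)
  (y_max - y_min) * plane + y_min
}

#' Pythagorean fuzzy negation
#'
#' The parametric negation `N(x; alpha) = alpha^2 (1 - x) /
#' (alpha^2 (1 - x) + x)`, a strictly decreasing involution-like map with
#' `N(0) = 1` and `N(1) = 0` for every `alpha > 0`. At `alpha = 1` it
#' reduces to the standard negation `1 - x`.
#'
#' @param x Numeric vector/matrix with values in `[0, 1]`.
#' @param alpha Positive scalar.
#' @return Same shape as `x`, values in `[0, 1]`.
#' @export
pfs_negation <- function(x, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a positive number", call. = FALSE)
  }
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("`x` must lie in [0, 1]", call. = FALSE)
  }
  a2 <- alpha^2
  a2 * (1 - x) / (a2 * (1 - x) + x)
}

#' Build a Pythagorean fuzzy image from a membership plane
#'
#' The PFS membership is `mu_pfs = 1 - N(mu; alpha)`, the non-membership
#' is the same negation applied to `mu_pfs`, and the indeterminacy is
#' `pi_pfs = sqrt(1 - mu_pfs^2 - nu_pfs^2)`. For `alpha` in `(0, 1]` the
#' Pythagorean constraint `mu_pfs^2 + nu_pfs^2 <= 1` holds pointwise.
#' The plane's defuzzification anchors are carried forward.
#'
#' @param plane A `membership_plane` (see [fuzzify()]).
#' @param alpha Fuzzification parameter in `(0, 1]`.
#' @return A list with class `"pfi"`: `mu_pfs`, `nu_pfs`, `pi_pfs`,
#'   `alpha`, `y_min`, `y_max`.
#' @export
build_pfi <- function(plane, alpha) {
  stopifnot(inherits(plane, "membership_plane"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  mu_pfs <- 1 - pfs_negation(plane$mu, alpha)
  nu_pfs <- pfs_negation(mu_pfs, alpha)
  # radicand is nonnegative analytically for alpha <= 1; pmax guards round-off
  pi_pfs <- sqrt(pmax(1 - mu_pfs^2 - nu_pfs^2, 0))
  structure(
    list(mu_pfs = mu_pfs, nu_pfs = nu_pfs, pi_pfs = pi_pfs, alpha = alpha,
         y_min = plane$y_min, y_max = plane$y_max),
    class = "pfi"
  )
}

#' Pythagorean fuzzy entropy of a PFI
#'
#' Mean over all pixels of
#' `(pi^2 + 1 - |mu^2 - nu^2|) / (pi^2 + 1 + |mu^2 - nu^2|)`.
#' Equals 1 wherever membership and non-membership coincide and 0 where
#' membership is total; always lies in `[0, 1]`.
#'
#' @param pfi A `pfi` object (see [build_pfi()]).
#' @return Scalar entropy in `[0, 1]`.
#' @export
pfe <- function(pfi) {
  stopifnot(inherits(pfi, "pfi"))
  d <- abs(pfi$mu_pfs^2 - pfi$nu_pfs^2)
  p2 <- pfi$pi_pfs^2
  mean((p2 + 1 - d) / (p2 + 1 + d))
}

#' Select the fuzzification parameter by entropy maximization
#'
#' Evaluates the Pythagorean fuzzy entropy of `build_pfi(plane, alpha)`
#' for every grid value and returns the maximizer (smallest such alpha on
#' ties) together with the full entropy curve.
#'
#' @param plane A `membership_plane`.
#' @param grid Strictly increasing vector of alpha values in `(0, 1]`
#'   (default `seq(0.01, 1, by = 0.01)`).
#' @return A list: `alpha_opt` scalar, `curve` tibble with columns
#'   `alpha` and `pfe`.
#' @export
optimize_alpha <- function(plane, grid = seq(0.01, 1, by = 0.01)) {
  stopifnot(inherits(plane, "membership_plane"))
  if (length(grid) == 0L) stop("`grid` must be nonempty", call. = FALSE)
  if (any(grid <= 0 | grid > 1)) stop("`grid` values must lie in (0, 1]", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  ent <- vapply(grid, function(a) pfe(build_pfi(plane, a)), numeric(1))
  list(alpha_opt = grid[which.max(ent)],
       curve = tibble::tibble(alpha = grid, pfe = ent))
}

#' Hedge and INT contrast enhancement of a PFI
#'
#' Raises the PFS membership plane to the hedge exponent `lambda`
#' (concentration for `lambda > 1`), then applies the piecewise-quadratic
#' INT intensification: `2 m^2` for `m <= 0.5`, `1 - 2 (1 - m)^2`
#' otherwise. Both steps fix 0 and 1 and are monotone, so ordering of
#' memberships is preserved. The PFI's defuzzification anchors are
#' carried forward.
#'
#' @param pfi A `pfi` object.
#' @param lambda_hedge Hedge exponent, `>= 1` (default 2).
#' @return A `membership_plane` with the enhanced memberships.
#' @export
enhance <- function(pfi, lambda_hedge = 2) {
  stopifnot(inherits(pfi, "pfi"))
  if (!is.numeric(lambda_hedge) || length(lambda_hedge) != 1L || lambda_hedge < 1) {
    stop("`lambda_hedge` must be >= 1", call. = FALSE)
  }
  m <- pfi$mu_pfs^lambda_hedge
  out <- ifelse(m <= 0.5, 2 * m^2, 1 - 2 * (1 - m)^2)
  structure(list(mu = out, y_min = pfi$y_min, y_max = pfi$y_max),
            class = "membership_plane")
}
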