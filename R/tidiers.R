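#' Tidy the entropy curves of a fusion result
#'
#' One row per (source image, alpha) pair with the Pythagorean fuzzy
#' entropy evaluated there, matching the per-alpha report layout used
#' when selecting the fuzzification parameter.
#'
#' @param x A `pfs_fusion` object.
#' @param ... Unused.
#' @return A tibble with columns `source`, `alpha`, `pfe`.
#' @export
tidy.pfs_fusion <- function(x, ...) {
  curves <- x$pfe_curves
  tibble::tibble(
    source = rep(c("x1", "x2"), vapply(curves, nrow, integer(1))),
    alpha = c(curves[[1]]$alpha, curves[[2]]$alpha),
    pfe = c(curves[[1]]$pfe, curves[[2]]$pfe)
  )
}

#' One-row summary of a fusion result
#'
#' The selected fuzzification parameters alongside the seven quality
#' metrics of the fused image against its sources.
#'
#' @param x A `pfs_fusion` object.
#' @param ... Unused.
#' @return A one-row tibble: `alpha_opt1`, `alpha_opt2`, then the
#'   [fusion_metrics()] columns.
#' @export
glance.pfs_fusion <- function(x, ...) {
  tibble::tibble(alpha_opt1 = x$alpha[1], alpha_opt2 = x$alpha[2], x$metrics)
}

#' Plot the per-alpha entropy curves of a fusion result
#'
#' Shows the Pythagorean fuzzy entropy of each source's base layer as a
#' function of the fuzzification parameter, with the selected optima
#' marked.
#'
#' @param object A `pfs_fusion` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfs_fusion <- function(object, ...) {
  d <- tidy(object)
  opt <- tibble::tibble(source = c("x1", "x2"), alpha = object$alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$alpha, y = .data$pfe,
                                  colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = opt,
                        ggplot2::aes(xintercept = .data$alpha,
                                     colour = .data$source),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = expression(alpha), y = "Pythagorean fuzzy entropy",
                  colour = "source") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
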