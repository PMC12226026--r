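#' Plot an internuclear persistence contour
#'
#' Draws the Gaussian-sum contour over a radius range, with the critical
#' values marked on the axis.
#'
#' @param ipc object from [build_ipc()].
#' @param from,to radius range, Angstrom; defaults pad the critical
#'   values by 5 sigma.
#' @param n evaluation points.
#' @return a ggplot object.
#' @export
plot_ipc <- function(ipc, from = NULL, to = NULL, n = 512) {
  if (length(ipc$values) == 0) {
    from <- from %||% 0
    to <- to %||% 1
  } else {
    from <- from %||% max(0, min(ipc$values) - 5 * ipc$sigma)
    to <- to %||% (max(ipc$values) + 5 * ipc$sigma)
  }
  x <- seq(from, to, length.out = n)
  df <- tibble(r = x, gamma = ipc_eval(ipc, x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$gamma)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(
      data = tibble(r = ipc$values), ggplot2::aes(x = .data$r),
      inherit.aes = FALSE, sides = "b"
    ) +
    ggplot2::labs(
      x = "filtration radius (Å)", y = expression(gamma(r)),
      title = sprintf("IPC, dimension %d (sigma = %g Å)", ipc$dimension, ipc$sigma)
    )
}

#' Plot a persistence fingerprint
#'
#' @param fp fingerprint tibble from [compute_fingerprint()].
#' @return a ggplot bar chart, one bar per component in spec order.
#' @export
plot_fingerprint <- function(fp) {
  fp$feature <- factor(fp$feature, levels = fp$feature)
  ggplot2::ggplot(fp, ggplot2::aes(x = .data$feature, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "IPC density") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a discretized IPC stack as a heatmap
#'
#' @param stack long tibble from [ipc_stack()].
#' @return a ggplot tile plot: bins on x, channels on y, density as fill.
#' @export
plot_ipc_stack <- function(stack) {
  stack$channel <- sprintf(
    "%s-%s dim %d", stack$protein_element, stack$ligand_element,
    stack$dimension
  )
  ggplot2::ggplot(stack, ggplot2::aes(
    x = (.data$lo + .data$hi) / 2, y = .data$channel, fill = .data$density
  )) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "filtration radius (Å)", y = NULL, fill = "density")
}

#' @rdname plot_ipc
#' @param object an `ipc` object.
#' @param ... passed on.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.ipc <- function(object, ...) plot_ipc(object, ...)

#' Plot feature importances of a boosted ensemble
#'
#' @param model `gbr_model`.
#' @param top show at most this many features.
#' @return a ggplot bar chart of mean-decrease-in-impurity importances.
#' @export
plot_importance <- function(model, top = 20) {
  imp <- head(gbr_importance(model), top)
  imp <- imp[imp$importance > 0, , drop = FALSE]
  imp$feature <- factor(imp$feature, levels = rev(imp$feature))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean decrease in impurity", y = NULL)
}
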