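#' Scatter of exposed proportion vs N/C YAP with marginal densities
#'
#' The standard view of the position-YAP relationship: one point per
#' blastomere, optionally coloured by group (e.g. control vs confined arm,
#' or cluster state), with marginal density panels when the patchwork
#' package is available.
#'
#' @param records data.frame with `prop_exposed` and `nc_yap`.
#' @param colour_by optional column name used for colour.
#' @param threshold optional horizontal N/C YAP threshold line.
#' @return a ggplot (or patchwork) object.
#' @export
plot_exposure_yap <- function(records, colour_by = NULL, threshold = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_exposure_yap requires ggplot2")
  }
  aes_pt <- if (is.null(colour_by)) {
    ggplot2::aes(x = .data$prop_exposed, y = .data$nc_yap)
  } else {
    ggplot2::aes(x = .data$prop_exposed, y = .data$nc_yap,
                 colour = .data[[colour_by]])
  }
  p <- ggplot2::ggplot(records, aes_pt) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "proportion of exposed surface area",
                  y = "N/C YAP ratio") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  if (requireNamespace("patchwork", quietly = TRUE)) {
    aes_x <- if (is.null(colour_by)) {
      ggplot2::aes(x = .data$prop_exposed)
    } else {
      ggplot2::aes(x = .data$prop_exposed, fill = .data[[colour_by]])
    }
    aes_y <- if (is.null(colour_by)) {
      ggplot2::aes(x = .data$nc_yap)
    } else {
      ggplot2::aes(x = .data$nc_yap, fill = .data[[colour_by]])
    }
    px <- ggplot2::ggplot(records, aes_x) +
      ggplot2::geom_density(alpha = 0.4) + ggplot2::theme_void() +
      ggplot2::theme(legend.position = "none")
    py <- ggplot2::ggplot(records, aes_y) +
      ggplot2::geom_density(alpha = 0.4) + ggplot2::coord_flip() +
      ggplot2::theme_void() + ggplot2::theme(legend.position = "none")
    p <- px + patchwork::plot_spacer() + p + py +
      patchwork::plot_layout(ncol = 2, widths = c(4, 1), heights = c(1, 4))
  }
  p
}
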