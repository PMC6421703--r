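# ggplot2 autoplot methods for the package's result types.

#' Plot a single walk curve
#'
#' @param object A `walk_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.walk_curve <- function(object, ...) {
  lab <- if (isTRUE(attr(object, "normalized"))) "normalized hit fraction" else "hit count"
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "rank", y = lab,
      title = paste0(curve_label(object), " (", attr(object, "kind"), ")"),
      subtitle = sprintf("N = %d, K = %d", attr(object, "N"), attr(object, "K"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the full curve family of one gene set
#'
#' Overlays the joint, null and conditional walks produced by
#' [walk_curves()], the per-set view used to read off dominance and
#' redundancy by eye.
#'
#' @param object An `mgsea_curves` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mgsea_curves <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$rank, y = .data$value, colour = .data$curve, linetype = .data$kind)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "rank", y = "normalized hit fraction", colour = "curve", linetype = "kind") +
    ggplot2::theme_minimal()
}

#' Heatmap of comparison p-values across gene sets
#'
#' @param object An `mgsea_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mgsea_result <- function(object, ...) {
  dat <- dplyr::mutate(
    object$comparisons,
    neg_log10_p = -log10(pmax(.data$p_value, 1e-300))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$comparison, y = .data$set, fill = .data$neg_log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a permutation FDR calibration curve
#'
#' @param object An `fdr_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fdr_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$threshold, y = .data$fdr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "p-value threshold", y = "false discovery rate",
      title = paste0("Permutation FDR (", attr(object, "feature"), ")")
    ) +
    ggplot2::theme_minimal()
}
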