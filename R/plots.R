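#' QR plot (quantile-rank) of a GWAS result set
#'
#' Observed s-values against significance rank, one panel per chromosome,
#' with the convex fit (solid over the fitted range, the projection is part
#' of the same curve) and the adaptive cutoff as a horizontal line.
#'
#' @param agws an `agws_result`.
#' @return a ggplot object.
#' @export
plot_qr <- function(agws) {
  dat <- qr_plot_data(agws)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$s), size = 0.4,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), color = "red") +
    ggplot2::geom_hline(yintercept = agws$agws, linetype = "dashed") +
    ggplot2::facet_wrap(~chrom) +
    ggplot2::labs(x = "rank / N", y = expression(-log[10](p)),
                  title = paste0("QR plot (", agws$analysis, "), aGWS = ",
                                 round(agws$agws, 3)))
}

#' @rdname plot_qr
#' @param object an `agws_result`.
#' @param ... unused.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.agws_result <- function(object, ...) plot_qr(object)

#' Manhattan plot of a GWAS result table
#'
#' @param results results tibble (`chrom`, `pos`, `s`).
#' @param cutoff optional horizontal significance line (e.g. an aGWS value).
#' @return a ggplot object.
#' @export
plot_manhattan <- function(results, cutoff = NULL) {
  dat <- results |>
    dplyr::mutate(chrom = factor(.data$chrom, unique(.data$chrom)))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos, y = .data$s,
                                         color = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x", switch = "x") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines")) +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](p)))
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}
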