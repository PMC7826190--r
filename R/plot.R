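#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a D frequency spectrum
#'
#' Renders the standard bar figure: one vertical bar per derived-allele
#' frequency bin at `x = k/n` with height `D_k`, bar width proportional to
#' the bin weight `w_k` (the full-width budget is spread over bins in
#' proportion to their weights), a dashed horizontal line at the overall D
#' and a solid zero line. Bins with no pattern mass are omitted.
#'
#' @param object A `dfs_result`.
#' @param full_width Total bar-width budget on the frequency axis
#'   (default 0.9; weights summing to 1 fill exactly this width).
#' @param fill Bar fill colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dfs_result <- function(object, full_width = 0.9,
                                fill = "#31688e", ...) {
  tbl <- object$tbl[!is.na(object$tbl$d_k), , drop = FALSE]
  if (nrow(tbl) == 0L) stop("no defined bins to plot", call. = FALSE)
  half <- tbl$w_k * full_width / 2
  tbl$xmin <- tbl$freq - half
  tbl$xmax <- tbl$freq + half
  tbl$ymin <- pmin(0, tbl$d_k)
  tbl$ymax <- pmax(0, tbl$d_k)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$freq, y = .data$d_k)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$d_overall, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax),
                       fill = fill, inherit.aes = FALSE) +
    ggplot2::labs(
      x = "derived allele frequency (k / n)",
      y = expression(D[k]),
      subtitle = sprintf("overall D = %.4f", object$d_overall)
    ) +
    ggplot2::theme_classic()
}

#' @rdname autoplot.dfs_result
#' @param x A `dfs_result`.
#' @export
plot_dfs <- function(x, ...) autoplot.dfs_result(x, ...)
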