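#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a type census
#'
#' @param object an `mt_census`.
#' @param ... unused.
#' @return a ggplot bar chart of record counts per arrangement type.
#' @export
autoplot.mt_census <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$type, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "arrangement type", y = "genomes") +
    ggplot2::theme_minimal()
}

#' Linear map of a circular gene order
#'
#' Draws the order as a horizontal bar of boxes from the anchor gene,
#' L-strand genes below the axis, box widths proportional to length
#' (unknown lengths drawn at the default size).
#'
#' @param order an `mt_order`.
#' @param anchor linearization anchor (default tRNA-Phe).
#' @return a ggplot object.
#' @export
plot_gene_order <- function(order, anchor = "F") {
  ord <- linearize(order, anchor)
  len <- ord$length_bp
  len[is.na(len)] <- default_token_length(ord$name[is.na(len)])
  end <- cumsum(as.numeric(len))
  df <- tibble::tibble(
    name = ord$name, category = ord$category,
    xmin = c(0, end[-length(end)]), xmax = end,
    ymin = ifelse(ord$strand > 0, 0, -1), ymax = ifelse(ord$strand > 0, 1, 0)
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$category),
                       colour = "white", linewidth = 0.2) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$xmin + .data$xmax) / 2,
                                    y = (.data$ymin + .data$ymax) / 2,
                                    label = .data$name),
                       size = 2.4, angle = 90) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  caption = "boxes below the axis: L-strand") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
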