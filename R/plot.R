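#' Heatmap of the cross-validation accuracy surface
#'
#' Tile plot of mean CV accuracy over the `(alpha, r)` grid explored by
#' [grid_search()], with the selected point marked.
#'
#' @param gs result of [grid_search()], or its `cv_table` data frame.
#' @return a ggplot object.
#' @export
plot_cv_surface <- function(gs) {
  tab <- if (is.data.frame(gs)) gs else gs$cv_table
  best <- if (is.data.frame(gs)) tab[which.max(tab$accuracy), ] else
    data.frame(alpha = gs$alpha, r = gs$r)
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$alpha), y = factor(.data$r),
                                    fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = best, ggplot2::aes(x = factor(.data$alpha),
                                                  y = factor(.data$r)),
                        inherit.aes = FALSE, shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(name = "CV accuracy") +
    ggplot2::labs(x = expression(alpha), y = "r",
                  title = "Cross-validated accuracy over the (alpha, r) grid") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom rlang .data
NULL
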