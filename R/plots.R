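#' @title Plots for selection results
#' @description ggplot2 methods: `autoplot()` for MGIDI fits and biplot
#'   decompositions, plus a correlation heatmap helper.
#' @name ideoselect-plots
NULL

#' @describeIn ideoselect-plots MGIDI distances ordered from closest to the
#'   ideotype, with the selected fraction highlighted and the cut-off drawn.
#' @param object An `"mgidi_result"` or `"index_biplot"`.
#' @param ... Unused.
#' @method autoplot mgidi_result
#' @export
autoplot.mgidi_result <- function(object, ...) {
  d <- tidy(object)
  cut <- max(d$MGIDI[d$selected])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$MGIDI,
                                  colour = .data$selected)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_hline(yintercept = cut, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey30"),
                                 name = "selected") +
    ggplot2::labs(x = "genotype (ranked by MGIDI)",
                  y = "multi-trait genotype-ideotype distance") +
    ggplot2::theme_minimal()
}

#' @describeIn ideoselect-plots Per-factor contribution (omega) bars for the
#'   selected genotypes; short bars are strengths.
#' @param result An `"mgidi_result"`.
#' @export
plot_contributions <- function(result) {
  sel <- result$selected$genotype
  d <- result$contributions %>% filter(.data$genotype %in% sel)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$omega,
                                  fill = .data$factor)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "share of squared ideotype distance",
                  fill = "factor") +
    ggplot2::theme_minimal()
}

#' @describeIn ideoselect-plots Genotype-by-index biplot on the first two
#'   axes: index vectors as arrows, genotypes as points.
#' @method autoplot index_biplot
#' @export
autoplot.index_biplot <- function(object, ...) {
  v <- object$axis_variance$variance_pct
  ggplot2::ggplot() +
    ggplot2::geom_point(data = object$genotype_coords,
                        ggplot2::aes(x = .data$axis1, y = .data$axis2),
                        colour = "grey40", size = 1.2) +
    ggplot2::geom_segment(data = object$index_coords,
                          ggplot2::aes(x = 0, y = 0, xend = .data$axis1,
                                       yend = .data$axis2),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "red") +
    ggplot2::geom_text(data = object$index_coords,
                       ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                    label = .data$index),
                       colour = "red", vjust = -0.6, size = 3) +
    ggplot2::labs(x = sprintf("axis I (%.1f%%)", v[1]),
                  y = sprintf("axis II (%.1f%%)", v[2])) +
    ggplot2::theme_minimal()
}

#' @describeIn ideoselect-plots Heatmap of a [correlate()] result.
#' @param corr Output of [correlate()].
#' @export
plot_correlations <- function(corr) {
  R <- attr(corr, "r_matrix")
  d <- as_tibble(as.data.frame(as.table(R)), .name_repair = "minimal")
  names(d) <- c("var1", "var2", "r")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$var1, y = .data$var2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
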