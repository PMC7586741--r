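#' Bar chart of exclusive intersection cells
#'
#' A compact alternative to an UpSet plot: one bar per exclusive membership
#' combination of the marked-gene sets, ordered by size.
#'
#' @param ic Result of [intersection_counts()].
#' @return A ggplot object.
#' @export
plot_intersection_counts <- function(ic) {
  df <- as_tibble(ic)
  df$combination <- factor(df$combination, levels = rev(df$combination))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$combination)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "genes in exclusive cell", y = NULL,
                  title = "Marked-gene set intersections") +
    ggplot2::theme_minimal()
}

#' Entropy distributions of target vs non-target genes
#'
#' @param x An `entropy_contrast` object.
#' @return A ggplot object (boxplot with jittered points).
#' @export
plot_entropy_contrast <- function(x) {
  ggplot2::ggplot(x$entropies,
                  ggplot2::aes(x = .data$group, y = .data$entropy,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::scale_fill_manual(values = c(target = "#7a0177",
                                          non_target = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "Shannon entropy",
                  subtitle = sprintf("rank-sum p = %.3g (%s)", x$p, x$direction)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_entropy_contrast
#' @param object,... Passed through for the `autoplot` method.
#' @method autoplot entropy_contrast
#' @export
autoplot.entropy_contrast <- function(object, ...) plot_entropy_contrast(object)

#' Pairwise signal scatter with fold-change calls highlighted
#'
#' Per-gene intensities of two samples on log axes; genes whose signal
#' differs by the fold threshold or more are highlighted, mirroring the
#' red-dot pairwise comparison panels of differential-marking analyses.
#'
#' @param x A `fold_comparison` object.
#' @return A ggplot object.
#' @export
plot_fold_comparison <- function(x) {
  tab <- x$table
  tab$called <- tab$status != "unchanged"
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$fpkb_a + x$pseudo,
                                    y = .data$fpkb_b + x$pseudo,
                                    colour = .data$called)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey50"),
                                 guide = "none") +
    ggplot2::labs(x = "FPKB sample A (+ pseudocount)",
                  y = "FPKB sample B (+ pseudocount)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_fold_comparison
#' @param object,... Passed through for the `autoplot` method.
#' @method autoplot fold_comparison
#' @export
autoplot.fold_comparison <- function(object, ...) plot_fold_comparison(object)

#' Per-bin count and significance overview for one contig
#'
#' @param bins Per-bin table with `count` and `q_value` columns.
#' @param contig Contig to display (default: the first).
#' @param fdr_threshold Significance threshold to mark.
#' @return A ggplot object.
#' @export
plot_bin_signal <- function(bins, contig = bins$contig[1],
                            fdr_threshold = 1e-25) {
  df <- bins[bins$contig == contig, , drop = FALSE]
  df$significant <- !is.na(df$q_value) & df$q_value <= fdr_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$count,
                                   fill = .data$significant)) +
    ggplot2::geom_col(width = df$width) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d95f02",
                                          `FALSE` = "grey70"),
                               guide = "none") +
    ggplot2::labs(x = paste("position on", contig), y = "fragments per bin") +
    ggplot2::theme_minimal()
}
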