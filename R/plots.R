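#' Heatmap of a connectome
#'
#' @param x A `connectome` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_connectome <- function(x, ...) {
  labels <- colnames(x)
  df <- tidyr::expand_grid(region_1 = labels, region_2 = labels)
  df$accordance <- as.vector(t(unclass(x)))
  df$region_1 <- factor(df$region_1, levels = labels)
  df$region_2 <- factor(df$region_2, levels = rev(labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_1, y = .data$region_2,
                                   fill = .data$accordance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "accordance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_connectome
#' @param object A `connectome` matrix.
#' @method autoplot connectome
#' @export
autoplot.connectome <- function(object, ...) plot_connectome(object, ...)

#' Volcano-style plot of edge-wise maturation statistics
#'
#' Edge-weight difference against -log10 adjusted p, with the FDR level
#' marked and circuitry-of-interest edges highlighted.
#'
#' @param object An `edge_stats` object from [paired_edge_ttest()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot edge_stats
#' @export
autoplot.edge_stats <- function(object, ...) {
  df <- tidy(object)
  alpha <- attr(object, "alpha")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ewd,
                                   y = -log10(.data$p_fdr),
                                   color = .data$in_coi)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "edge weight difference (session 2 - session 1)",
                  y = expression(-log[10] ~ "FDR-adjusted p"),
                  color = "in COI") +
    ggplot2::theme_minimal()
}

#' Bar plot of group z-score differences on the circuitry of interest
#'
#' @param object A `group_diff` object from [music_effect_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_diff
#' @export
autoplot.group_diff <- function(object, ...) {
  df <- tidy(object)
  df$edge <- paste(df$region_1, df$region_2, sep = " - ")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$edge,
                                                      .data$z_diff),
                                   y = .data$z_diff,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "z_threshold"),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "z-score difference (music - control) / sqrt(2)",
                  fill = "significant") +
    ggplot2::theme_minimal()
}

#' QC trace plot: FD and DVARS with censored volumes shaded
#'
#' @param object A `qc_trace` tibble from [scrub_session()].
#' @param params A [qc_params()] supplying the threshold lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qc_trace
#' @export
autoplot.qc_trace <- function(object, params = qc_params(), ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(unclass(object))[c("volume", "fd", "dvars_pct",
                                         "keep")],
    c("fd", "dvars_pct"), names_to = "metric")
  thr <- tibble::tibble(metric = c("fd", "dvars_pct"),
                        threshold = c(params$fd_threshold,
                                      params$dvars_threshold))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$volume, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(data = df[!df$keep, ], color = "red", size = 0.6) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "volume", y = NULL) +
    ggplot2::theme_minimal()
}
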