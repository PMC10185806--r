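#' Heatmap of a functional connectivity matrix
#'
#' ROI-by-ROI tile plot in canonical order with network boundaries drawn;
#' the diverging palette is centered at zero so anti-correlations read as
#' blue blocks.
#'
#' @param m Symmetric FC matrix in canonical ROI order.
#' @param parcellation A [parcellation()] (for network boundary lines).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_fc_matrix <- function(m, parcellation = NULL, title = NULL) {
  n <- nrow(m)
  rois <- rownames(m) %||% paste0("roi", seq_len(n))
  df <- tidyr::expand_grid(row = seq_len(n), col = seq_len(n)) %>%
    mutate(z = as.vector(.env$m))
  lim <- max(abs(df$z))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "white", high = "#B2182B",
      limits = c(-lim, lim), name = "Fisher z"
    ) +
    ggplot2::scale_y_reverse(breaks = seq_len(n), labels = rois) +
    ggplot2::scale_x_continuous(
      breaks = seq_len(n), labels = rois,
      guide = ggplot2::guide_axis(angle = 90)
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal(base_size = 8)
  if (!is.null(parcellation)) {
    edges <- cumsum(network_sizes(parcellation)) + 0.5
    edges <- edges[-length(edges)]
    p <- p +
      ggplot2::geom_vline(xintercept = edges, linewidth = 0.3) +
      ggplot2::geom_hline(yintercept = edges, linewidth = 0.3)
  }
  p
}

#' MPFC model-selection curve
#'
#' @param quality Quality tibble from [select_k()] (or a `dfc_k_selection` /
#'   `dfc_run` object).
#' @return A ggplot object with the MPFC peak highlighted.
#' @export
plot_mpfc <- function(quality) {
  if (inherits(quality, "dfc_k_selection")) quality <- quality$quality
  if (inherits(quality, "dfc_run")) quality <- quality$quality
  if (is.null(quality)) abort("No MPFC scan available (fixed-k fit).")
  k_opt <- quality$k[which.max(quality$mpfc)]
  ggplot2::ggplot(quality, ggplot2::aes(.data$k, .data$mpfc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(
      data = filter(quality, .data$k == k_opt),
      color = "#B2182B", size = 3
    ) +
    ggplot2::labs(
      x = "Number of states (k)", y = "MPFC",
      title = paste0("MPFC peak at k = ", k_opt)
    ) +
    ggplot2::theme_minimal()
}

#' Fraction- and dwell-time bars by group
#'
#' @param temporal Tibble from [temporal_metrics()].
#' @param behavior Behavior tibble with `subject` and `group`.
#' @return A ggplot object: per-state bars (group mean +/- SE) for fraction
#'   and dwell time.
#' @export
plot_temporal <- function(temporal, behavior) {
  df <- left_join(temporal, behavior[c("subject", "group")], by = "subject") %>%
    tidyr::pivot_longer(c("fraction_time", "dwell_windows"),
      names_to = "metric", values_to = "value"
    ) %>%
    group_by(.data$metric, .data$state, .data$group) %>%
    summarise(
      mean = mean(.data$value),
      se = sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    factor(.data$state), .data$mean,
    fill = .data$group
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$se,
        ymax = .data$mean + .data$se
      ),
      position = ggplot2::position_dodge(0.9), width = 0.2
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "State", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_mpfc `autoplot` method for `dfc_k_selection`.
#' @param object,... Passed on.
#' @export
autoplot.dfc_k_selection <- function(object, ...) plot_mpfc(object)

#' @describeIn plot_fc_matrix `autoplot` method for a `dfc_state_model`
#'   (panels one state's centroid; `state` picks which).
#' @param object A `dfc_state_model`.
#' @param state State index to plot.
#' @param ... Unused.
#' @export
autoplot.dfc_state_model <- function(object, state = 1, ...) {
  plot_fc_matrix(
    object$centroid_matrices[[state]],
    title = paste("State", state, "centroid")
  )
}
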