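#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  lab <- object$node_labels
  df <- tidyr::expand_grid(from = lab, to = lab)
  df$weight <- as.vector(t(object$W))  # row-major to match expand_grid order
  sc <- if (object$scope == "within") object$band else
    paste(object$band, object$band_b, sep = "-")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$to, lab),
                                   y = factor(.data$from, rev(lab)),
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = if (object$order == "low")
      c(0, 1) else c(-1, 1)) +
    ggplot2::labs(title = sprintf("%s-order connectivity (%s)",
                                  object$order, sc),
                  x = NULL, y = NULL, fill = "weight") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' @export
autoplot.supra_adjacency <- function(object, ...) {
  lab <- colnames(object$S)
  df <- tidyr::expand_grid(from = lab, to = lab)
  df$weight <- as.vector(t(object$S))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$to, lab),
                                   y = factor(.data$from, rev(lab)),
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = "supra-adjacency matrix", x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_text(size = 5),
                   axis.text.x = ggplot2::element_text(angle = 90))
}

#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- tidy(object)
  df$item <- factor(df$item, levels = df$item[order(df$t)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$item,
                                   color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(title = attr(object, "family_id"),
                  x = sprintf("t (%s vs %s)", attr(object, "group_a"),
                              attr(object, "group_b")),
                  y = NULL, color = sprintf("q <= %g",
                                            attr(object, "q_star"))) +
    ggplot2::theme_minimal()
}

#' Plot an integration/segregation state sequence
#'
#' @param states A [classify_states()] result.
#' @param window_starts_s Optional window start times (seconds).
#' @return A ggplot object.
#' @export
plot_state_sequence <- function(states, window_starts_s = NULL) {
  stopifnot(inherits(states, "state_sequence"))
  x <- if (is.null(window_starts_s)) seq_along(states) else window_starts_s
  df <- tibble::tibble(window = x, state = as.integer(unclass(states)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window, y = .data$state)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = c(0, 1),
                                labels = c("segregation", "integration")) +
    ggplot2::labs(x = if (is.null(window_starts_s)) "window" else
      "time (s)", y = NULL,
      title = sprintf("state sequence (SE = %.3f)", state_entropy(states))) +
    ggplot2::theme_minimal()
}

#' Plot per-band graph metrics by group
#'
#' @param metrics The `metrics` tibble of a [run_pipeline()] bundle, joined
#'   with group labels (columns `band`, `order`, `cc`, `cpl`, `ge`, `le`,
#'   `group`).
#' @param order Which network order to show.
#' @return A ggplot object (boxplots per band x metric).
#' @export
plot_metrics <- function(metrics, order = "low") {
  df <- dplyr::filter(metrics, .data$order == !!order)
  df <- tidyr::pivot_longer(df, cols = c("cc", "cpl", "ge", "le"),
                            names_to = "metric", values_to = "value")
  df <- dplyr::filter(df, is.finite(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = sprintf("%s-order network metrics", order),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
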