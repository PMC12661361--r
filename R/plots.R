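#' Plot voltage-time traces
#'
#' Overlays the traces of selected sensors, coloured by sample class, with
#' the measurement phase boundaries (fan on, sample removed, fan off) marked.
#'
#' @param signals Long signal tibble (raw or preprocessed).
#' @param meta Sample metadata (for class colours); optional.
#' @param sensor_ids Sensors to show (default: first 4 present).
#' @param timeline An [measurement_timeline()]; draws phase boundaries.
#' @return A ggplot object.
#' @export
plot_signals <- function(signals, meta = NULL, sensor_ids = NULL,
                         timeline = measurement_timeline()) {
  check_signals(signals)
  if (is.null(sensor_ids)) {
    sensor_ids <- utils::head(sort(unique(signals$sensor_id)), 4)
  }
  df <- signals[signals$sensor_id %in% sensor_ids, , drop = FALSE]
  df$trace <- interaction(df[signal_keys(df)], drop = TRUE)
  if (!is.null(meta) && "class_label" %in% names(meta)) {
    df$class_label <- meta$class_label[match(df$sample_id, meta$sample_id)]
  } else {
    df$class_label <- "signal"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$voltage_v,
                                   group = .data$trace,
                                   colour = .data$class_label)) +
    ggplot2::geom_vline(
      xintercept = c(timeline$fan_on, timeline$sample_removed,
                     timeline$fan_off),
      linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sensor_id),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "voltage (V)", colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot a sensor-utility ranking
#'
#' Bar chart of per-sensor similarity coefficients, ordered by utility rank;
#' the least useful sensors (highest similarity) are highlighted.
#'
#' @param object A `sensor_utility` table from [rank_sensors()].
#' @param highlight_worst How many least-useful sensors to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sensor_utility
#' @export
autoplot.sensor_utility <- function(object, highlight_worst = 2L, ...) {
  df <- dplyr::mutate(
    object,
    worst = .data$rank > nrow(object) - highlight_worst)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(factor(.data$sensor_id), .data$rank),
    y = .data$similarity, fill = .data$worst)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "goldenrod"),
                               guide = "none") +
    ggplot2::labs(x = "sensor (by utility rank)",
                  y = "similarity coefficient (mean cross-class Pearson r)") +
    ggplot2::theme_minimal()
}

#' Plot an elimination performance matrix
#'
#' Validation metrics against the number of sensors removed.
#'
#' @param object A `performance_matrix` from [iterative_elimination()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot performance_matrix
#' @export
autoplot.performance_matrix <- function(object, ...) {
  df <- object |>
    dplyr::select("k", "accuracy", "sensitivity", "specificity") |>
    tidyr::pivot_longer(-"k", names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sensors removed (least useful first)",
                  y = "validation metric") +
    ggplot2::theme_minimal()
}

#' Plot a learning curve
#'
#' @param data A tibble from [learning_curve()].
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$fraction, y = .data$accuracy,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "fraction of training samples", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
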