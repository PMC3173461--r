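#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot response-group mean profiles
#'
#' Mean log2 fold-change profile per cluster group across sampling days.
#'
#' @param object A clustered `pi_de` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pi_de
#' @export
autoplot.pi_de <- function(object, ...) {
  fc_cols <- grep("^fc_d", names(object), value = TRUE)
  days <- as.integer(sub("^fc_d", "", fc_cols))
  long <- object |>
    dplyr::filter(!is.na(.data$group)) |>
    tidyr::pivot_longer(dplyr::all_of(fc_cols), names_to = "day_col",
                        values_to = "fc") |>
    dplyr::mutate(day = days[match(.data$day_col, fc_cols)],
                  log2_fc = log2(.data$fc)) |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(mean_log2_fc = mean(.data$log2_fc), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$mean_log2_fc,
                                     colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Days after Pi withdrawal",
                  y = "Mean log2 fold change (treated / control)",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Plot per-sample margin values
#'
#' Bar chart of SVM margins; positive bars predict Pi deficient samples,
#' negative Pi replete.
#'
#' @param object A `pi_margins` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pi_margins
#' @export
autoplot.pi_margins <- function(object, ...) {
  object$sample_id <- factor(object$sample_id, levels = object$sample_id)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample_id,
                                       y = .data$margin,
                                       fill = .data$predicted_class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "Margin value (positive = Pi deficient)",
                  fill = "Predicted") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Plot the evaluation grid
#'
#' Percent-correct heat map over kernel and diagnostic-set size.
#'
#' @param object A `pi_grid` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pi_grid
#' @export
autoplot.pi_grid <- function(object, ...) {
  object$k <- factor(object$k, levels = sort(unique(object$k)))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$kernel,
                                       fill = .data$percent_correct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$percent_correct)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "Diagnostic genes used", y = NULL,
                  fill = "% correct") +
    ggplot2::theme_minimal()
}
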