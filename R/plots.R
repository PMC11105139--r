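# ggplot2 displays for metrics reports and prevalence comparisons.

#' Plot a metrics report
#'
#' Dot plot of F1, PPV, sensitivity and specificity per condition row, with
#' bootstrap interval bars when the report carries them.
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  rows <- object$rows
  rows$task <- ifelse(
    is.na(rows$status), rows$condition_id,
    paste0(rows$condition_id, " [", rows$status, "]")
  )
  long <- tidyr::pivot_longer(
    rows, dplyr::all_of(metric_names),
    names_to = "metric", values_to = "value"
  )
  has_ci <- all(paste0(metric_names, "_low") %in% names(rows))
  if (has_ci) {
    lows <- tidyr::pivot_longer(
      rows[c("task", paste0(metric_names, "_low"))],
      -"task", names_to = "metric", values_to = "low"
    )
    lows$metric <- sub("_low$", "", lows$metric)
    highs <- tidyr::pivot_longer(
      rows[c("task", paste0(metric_names, "_high"))],
      -"task", names_to = "metric", values_to = "high"
    )
    highs$metric <- sub("_high$", "", highs$metric)
    long <- long |>
      dplyr::left_join(lows, by = c("task", "metric")) |>
      dplyr::left_join(highs, by = c("task", "metric"))
  }
  p <- ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$value, y = .data$task)
  ) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, nrow = 1) +
    ggplot2::labs(
      x = "%", y = NULL,
      title = paste0("Detection performance (", object$level, " level)")
    ) +
    ggplot2::theme_minimal()
  if (has_ci) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$low, xmax = .data$high),
      height = 0.2, na.rm = TRUE
    )
  }
  p
}

#' Compare per-condition prevalence across sources
#'
#' Bar chart of per-condition prevalence estimated from several sources of
#' stay predictions (eg, NLP pipeline vs claim codes vs gold chart review).
#'
#' @param predictions A named list of stay-prediction tibbles.
#' @return A ggplot object.
#' @export
plot_prevalence <- function(predictions) {
  stopifnot(length(predictions) >= 1L, !is.null(names(predictions)))
  long <- purrr::imap_dfr(predictions, function(p, name) {
    est <- estimate_prevalence(p)
    est$source <- name
    est
  })
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$prevalence, y = .data$condition_id, fill = .data$source
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "prevalence", y = NULL, fill = "source") +
    ggplot2::theme_minimal()
}
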