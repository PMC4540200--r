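# ggplot2 display methods for the package's result types

#' Scatter plot of a condition comparison
#'
#' Mean log2 expression of control vs treated libraries, one point per miRNA;
#' consistently deregulated miRNAs are highlighted. Mirrors the standard
#' log2-log2 expression scatter used to spot reproducibly shifted miRNAs
#' against an otherwise diagonal cloud.
#'
#' @param object A `mirna_comparison` from [compare_conditions()]; the plot
#'   also needs the normalized table via the `normalized` argument.
#' @param normalized Normalized tibble used to build the comparison.
#' @param control,treated Library name vectors, as in [compare_conditions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirna_comparison <- function(object, normalized, control, treated, ...) {
  means <- normalized |>
    mutate(condition = dplyr::case_when(
      .data$library %in% control ~ "control",
      .data$library %in% treated ~ "treated",
      TRUE ~ NA_character_)) |>
    filter(!is.na(.data$condition)) |>
    group_by(.data$name, .data$condition) |>
    summarise(log2_value = mean(.data$log2_value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "log2_value") |>
    left_join(tidy(object)[c("name", "consistently_deregulated")], by = "name")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$control, y = .data$treated,
                                      colour = .data$consistently_deregulated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(shape = 4, size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red"),
                                 name = "consistent") +
    ggplot2::labs(x = "control, log2(normalized + 2)",
                  y = "treated, log2(normalized + 2)")
}

#' ROC curve plot
#'
#' @param object A `roc_curve` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc))
}

#' Cohort box plot with 5th-95th percentile whiskers
#'
#' Log2 relative expression of one target per group, drawn as a box
#' (quartiles and median) with whiskers at the 5th and 95th percentiles --
#' the conventional presentation for placental qPCR panels.
#'
#' @param samples Long cohort sample sheet.
#' @param target Target to plot.
#' @param reference_target Normalizer (default `"U6"`).
#' @param unit Observation unit (see [aggregate_expression()]).
#' @return A ggplot object.
#' @export
plot_cohort_box <- function(samples, target, reference_target = "U6",
                            unit = "placenta") {
  agg <- aggregate_expression(samples, target, reference_target, unit)
  agg$log2_rel <- log2(agg$rel_expr)
  stats <- agg |>
    group_by(.data$group) |>
    summarise(box_summary(.data$log2_rel), .groups = "drop")
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                           width = 0.2) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q1,
                                        ymax = .data$q3),
                           width = 0.5, fill = "grey90") +
    ggplot2::labs(x = NULL, y = sprintf("log2(%s / %s)", target, reference_target),
                  title = target)
}
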