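#' @importFrom ggplot2 ggplot aes geom_col geom_point geom_line geom_hline
#'   geom_errorbar geom_abline labs theme_minimal scale_y_continuous autoplot
NULL

#' @export
ggplot2::autoplot

#' Completeness per form before/after pre-processing
#'
#' @param before,after `completeness()` results carrying `per_form`.
#' @return A ggplot bar chart.
#' @export
plot_completeness <- function(before, after) {
  df <- bind_rows(
    mutate(attr(before, "per_form"), stage = "before"),
    mutate(attr(after, "per_form"), stage = "after"))
  ggplot(df, aes(x = .data$form, y = .data$completeness, fill = .data$stage)) +
    geom_col(position = "dodge") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "form", y = "fraction of cells observed",
         title = "Completeness by form") +
    theme_minimal()
}

#' @export
autoplot.hd_imputation_report <- function(object, ...) {
  ggplot(object, aes(x = .data$rank, y = .data$final_score,
                     colour = .data$dtype, shape = .data$chosen_family)) +
    geom_point(size = 3) +
    labs(x = "imputation order", y = "CV score (R2 / weighted F1)",
         title = "Imputation model selection") +
    theme_minimal()
}

#' @export
autoplot.hd_model_evaluation <- function(object, ...) {
  r <- rank_models(object)
  ggplot(r, aes(x = stats::reorder(.data$model, .data$rmse), y = .data$rmse)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$rmse - .data$rmse_sd,
                      ymax = .data$rmse + .data$rmse_sd), width = 0.2) +
    labs(x = NULL, y = "RMSE (years)", title = "AAO prediction benchmark") +
    theme_minimal() +
    ggplot2::coord_flip()
}

#' @export
autoplot.hd_calibration_bands <- function(object, ...) {
  ggplot(object, aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                     y = .data$accuracy)) +
    geom_col(width = 0.09) +
    labs(x = "predicted probability", y = "band accuracy",
         title = "Calibration bands") +
    theme_minimal()
}

#' @export
autoplot.hd_driving_evaluation <- function(object, ...) {
  roc <- roc_points(object$scores$label, object$scores$score)
  ggplot(roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "false positive rate", y = "true positive rate",
         title = "Driving-capability ROC") +
    theme_minimal()
}

#' @export
autoplot.hd_trajectory <- function(object, ...) {
  ggplot(object, aes(x = .data$slot)) +
    geom_line(aes(y = .data$probability), colour = "orange") +
    geom_point(aes(y = .data$probability,
                   shape = .data$type), colour = "orange", size = 3) +
    geom_line(data = object[!is.na(object$recorded), ],
              aes(y = .data$recorded), colour = "steelblue") +
    geom_hline(yintercept = 0.5, linetype = "dashed") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "visit slot", y = "driving capability",
         title = "Personalised driving trajectory") +
    theme_minimal()
}
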