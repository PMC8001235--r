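# ggplot2 autoplot methods

#' @exportS3Method ggplot2::autoplot
autoplot.edison_survival <- function(object, ...) {
  km <- object$km
  base <- dplyr::bind_rows(
    tibble::tibble(group = unique(km$group), time = 0, survival = 1),
    dplyr::select(km, "group", "time", "survival")
  )
  ggplot2::ggplot(base,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = factor(.data$group))) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time", y = "Survival probability", colour = "Flag",
      title = sprintf("Kaplan-Meier by immune-evasion flag (%s)",
                      object$endpoint),
      subtitle = sprintf("log-rank p = %.3g; HR = %.2f [%.2f, %.2f]",
                         object$logrank$p_value, object$cox$hr,
                         object$cox$ci_low, object$cox$ci_high)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.model_comparison <- function(object, ...) {
  res <- object$results
  res$id <- paste(res$dataset, res$model, sep = "\n")
  ggplot2::ggplot(res, ggplot2::aes(x = .data$id)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$mcc_cv, ymin = .data$mcc_cv_low,
                   ymax = .data$mcc_cv_high, colour = "CV (95% CI)")) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$mcc_test, colour = "Test"), shape = 17,
      size = 3) +
    ggplot2::labs(x = NULL, y = "MCC", colour = NULL,
                  title = "Model comparison by Matthews correlation") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.boruta_result <- function(object, top_n = 30, ...) {
  s <- dplyr::arrange(object$summary, dplyr::desc(.data$fraction))
  s <- head(s, top_n)
  s$feature <- factor(s$feature, levels = rev(s$feature))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$fraction, y = .data$feature,
                                  fill = .data$decision)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$config$consensus_fraction,
                        linetype = 2) +
    ggplot2::labs(x = "Fraction of runs confirmed", y = NULL,
                  title = "Shadow-feature selection consensus") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.model_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$roc_curve,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (%s), AUC = %.3f", object$family,
                                  object$auc_test)) +
    ggplot2::theme_minimal()
}
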