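#' Plot per-condition acceptance rates
#'
#' @param trials Trial tibble with choices.
#' @return A ggplot: subject-level acceptance rates by scenario and
#'   conduct, with group means.
#' @export
plot_acceptance <- function(trials) {
  df <- trials |>
    mutate(condition = trial_condition(trials),
           y = choice_to_binary(.data$choice)) |>
    summarise(rate = mean(.data$y), .by = c("subject_id", "condition")) |>
    mutate(scenario = ifelse(substr(.data$condition, 1, 1) == "D",
                             "Dyad", "Solo"),
           conduct = ifelse(substr(.data$condition, 2, 2) == "B",
                            "Bribe", "Control"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conduct, y = .data$rate,
                                   colour = .data$conduct)) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4, colour = "black") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Acceptance rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @exportS3Method ggplot2::autoplot
autoplot.mc_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "Group-level posterior (mean and 95% CI)", y = NULL,
                  title = paste0("Model ", object$model$model_id, ": ",
                                 object$model$name)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mc_recovery <- function(object, ...) {
  labs <- object$correlations |>
    mutate(label = sprintf("r = %.2f", .data$r))
  ggplot2::ggplot(object$scatter,
                  ggplot2::aes(x = .data$generating, y = .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60",
                         linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_text(data = labs, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.2, vjust = 1.4,
                       inherit.aes = FALSE) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Generating value", y = "Recovered value") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mc_ppc <- function(object, ...) {
  labs <- object$correlations |>
    mutate(label = sprintf("r = %.2f", .data$r))
  ggplot2::ggplot(object$proportions,
                  ggplot2::aes(x = .data$predicted, y = .data$actual)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60",
                         linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_text(data = labs, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.2, vjust = 1.4,
                       inherit.aes = FALSE) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "Predicted acceptance", y = "Actual acceptance",
                  title = paste0("Posterior predictive check (",
                                 object$mode, ")")) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mc_rdm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$subject_a),
                                   y = factor(.data$subject_b),
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = attr(object, "metric_label")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @exportS3Method ggplot2::autoplot
autoplot.mc_loso <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60",
                         linetype = 2) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf(
                    "LOSO decoding: accuracy %.1f%%, AUC %.2f, p = %.3g",
                    100 * object$accuracy, object$auc, object$p)) +
    ggplot2::theme_minimal()
}
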