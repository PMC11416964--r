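# ggplot2 views of the result types.

#' Plot prediction accuracies per trait and method
#'
#' @param object a `gp_accuracy` tibble from [evaluate_methods()].
#' @param ... unused.
#' @return a ggplot: mean accuracy with standard-error bars.
#' @export
autoplot.gp_accuracy <- function(object, ...) {
  s <- summarize_accuracy(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$trait, y = .data$mean_r,
                                  fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_r - .data$se_r,
                   ymax = .data$mean_r + .data$se_r),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "prediction accuracy (Pearson r)",
                  fill = "method") +
    ggplot2::theme_minimal()
}

#' Plot the GEBV distribution of predicted crosses
#'
#' @param object a `cross_table`.
#' @param groups optional group assignment to colour crosses by heterotic
#'   category.
#' @param ... unused.
#' @return a ggplot density / histogram of GEBVs.
#' @export
autoplot.cross_table <- function(object, groups = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(groups)) {
    if (is.data.frame(groups)) groups <- setNames(groups$group, groups$line_id)
    df$category <- canonical_pair_id(unname(groups[df$parent1]),
                                     unname(groups[df$parent2]))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$gebv, fill = .data$category)) +
      ggplot2::geom_density(alpha = 0.5) +
      ggplot2::labs(x = "predicted GEBV", y = "density",
                    fill = "heterotic pattern") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$gebv)) +
      ggplot2::geom_histogram(bins = 60) +
      ggplot2::labs(x = "predicted GEBV", y = "crosses") +
      ggplot2::theme_minimal()
  }
}

#' Plot heterotic-pattern category means
#'
#' @param object a `heterotic_summary`.
#' @param ... unused.
#' @return a ggplot of per-category mean GEBV with sd bars.
#' @export
autoplot.heterotic_summary <- function(object, ...) {
  df <- object$categories
  df$category <- factor(df$category, levels = df$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$mean_gebv)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_gebv - .data$sd_gebv,
                   ymax = .data$mean_gebv + .data$sd_gebv), width = 0.2) +
    ggplot2::geom_hline(yintercept = object$overall_mean, linetype = 2) +
    ggplot2::labs(x = "heterotic pattern", y = "mean predicted GEBV") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Heritability versus accuracy scatterplot
#'
#' @param report a `gp_accuracy` tibble.
#' @param h2 per-trait heritabilities (named vector or `trait`/`h2`
#'   tibble).
#' @return a ggplot with the fitted correlation in the subtitle.
#' @export
plot_h2_accuracy <- function(report, h2) {
  if (is.data.frame(h2)) h2 <- setNames(h2$h2, h2$trait)
  acc <- report |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(mean_r = mean(.data$r), .groups = "drop") |>
    dplyr::mutate(h2 = unname(h2[.data$trait]))
  stats <- correlate_h2_accuracy(report, h2)
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$h2, y = .data$mean_r)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = expression(hat(h)^2), y = "mean prediction accuracy",
                  subtitle = sprintf("R = %.3f, p = %.2g", stats$R, stats$p_value)) +
    ggplot2::theme_minimal()
}
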