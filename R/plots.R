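# ggplot2 autoplot methods for the main result types.

#' Plot mediation bootstrap results
#'
#' Forest-style plot of the total, direct and indirect effects with their
#' bootstrap confidence intervals.
#'
#' @param object A [bootstrap_effects()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mediation_boot <- function(object, ...) {
  d <- object$intervals
  d$effect <- factor(d$effect, levels = rev(c("a", "b", "total", "direct", "indirect")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$effect)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower, xmax = .data$upper)) +
    ggplot2::labs(
      x = "estimate",
      y = NULL,
      title = sprintf(
        "Mediation effects (%s %d%% CI, %d resamples)",
        gsub("_", "-", object$settings$method),
        round(100 * object$settings$level), object$settings$n_boot
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot conditional (simple) effects across moderator levels
#'
#' Lines of the first-stage, second-stage and conditional indirect effects
#' against the moderator level, with bootstrap interval ribbons when
#' available.
#'
#' @param object A [simple_effects()] or [bootstrap_conditional()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conditional_effects <- function(object, ...) {
  d <- tidyr::pivot_longer(object$table,
    c("first_stage", "second_stage", "indirect"),
    names_to = "quantity", values_to = "estimate"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$w, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "moderator level (SD units)", y = "simple effect") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.conditional_effects
#' @export
autoplot.conditional_boot <- function(object, ...) {
  d <- dplyr::filter(object$intervals, .data$level != "high - low")
  d$w <- object$settings$levels[match(
    d$level,
    object$point$table$level
  )]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$w, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = "moderator level (SD units)", y = "conditional effect",
      title = sprintf(
        "Conditional effects (%s %d%% CI, %d resamples)",
        gsub("_", "-", object$settings$method),
        round(100 * object$settings$level), object$settings$n_boot
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a correlation matrix
#'
#' Tile heatmap of a [pearson_matrix()] with correlation labels.
#'
#' @param object A [pearson_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pearson_matrix <- function(object, ...) {
  vars <- rownames(object$r)
  d <- tidyr::expand_grid(var1 = vars, var2 = vars)
  d$r <- as.vector(t(object$r))
  d$var1 <- factor(d$var1, levels = vars)
  d$var2 <- factor(d$var2, levels = rev(vars))
  ggplot2::ggplot(d, ggplot2::aes(.data$var1, .data$var2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
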