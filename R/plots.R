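# ggplot2 displays for the main result types.

#' Plot an agreement chart
#'
#' Draws the Bangdiwala geometry produced by [build_agreement_chart()]:
#' marginal rectangles, gray one-level-off partial-agreement zones and black
#' exact-agreement squares, on a square n x n canvas.
#'
#' @param object an `agreement_chart`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.agreement_chart <- function(object, ...) {
  ggplot() +
    geom_rect(data = object$rectangles,
              aes(xmin = .data$x0, xmax = .data$x1,
                  ymin = .data$y0, ymax = .data$y1),
              fill = "white", colour = "black", linewidth = 0.3) +
    geom_rect(data = object$gray_zones,
              aes(xmin = .data$x0, xmax = .data$x1,
                  ymin = .data$y0, ymax = .data$y1),
              fill = "grey70") +
    geom_rect(data = object$black_squares,
              aes(xmin = .data$x0, xmax = .data$x1,
                  ymin = .data$y0, ymax = .data$y1),
              fill = "black") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey40") +
    coord_equal(xlim = c(0, object$n), ylim = c(0, object$n)) +
    labs(x = "classifier A (cumulative count)",
         y = "classifier B (cumulative count)") +
    theme_minimal()
}

#' Stacked class-proportion bars per assessment group
#'
#' @param props output of [proportions_by()].
#' @param signature optional single signature to display.
#' @return a ggplot.
#' @export
plot_class_proportions <- function(props, signature = NULL) {
  if (!is.null(signature))
    props <- filter(props, .data$signature == !!signature)
  ggplot(props, aes(x = .data$group, y = .data$fraction,
                    fill = .data$class)) +
    geom_col(position = "stack") +
    facet_wrap(~signature) +
    labs(x = NULL, y = "fraction of classified samples") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Kaplan-Meier step curves
#'
#' @param object a `km_curve` from [km_estimate()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$estimate,
                     colour = .data$group)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "years", y = "overall survival", colour = NULL) +
    theme_minimal()
}

#' Forest plot of per-class hazard ratios
#'
#' @param ft a [forest_table()] tibble.
#' @return a ggplot with a log-scaled HR axis.
#' @export
plot_forest <- function(ft) {
  ft <- mutate(ft, label = paste(.data$signature, .data$class, sep = ": "))
  ggplot(ft, aes(x = .data$hr, y = .data$label)) +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_point() +
    scale_x_log10() +
    facet_wrap(~group, scales = "free_y") +
    labs(x = "hazard ratio (95% CI)", y = NULL) +
    theme_minimal()
}
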