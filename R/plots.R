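# ggplot2 displays for the package's result types.

#' Plot distance summaries by GET score and phase
#'
#' Mean 3-D distance to the paired turbine hub against a GET score, split by
#' operational phase, with the empirical 95% data range as a ribbon.
#'
#' @param records A before/after proximity tibble.
#' @param score Which score to plot against: `"get_turbine"` or
#'   `"get_location"`.
#' @return A ggplot.
#' @export
plot_distance_by_get <- function(records,
                                 score = c("get_turbine", "get_location")) {
  score <- match.arg(score)
  dat <- records %>%
    group_by(score = .data[[score]], .data$phase) %>%
    summarise(mean = mean(.data$d3d),
              lo = as.numeric(quantile(.data$d3d, 0.025)),
              hi = as.numeric(quantile(.data$d3d, 0.975)),
              .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, y = .data$mean,
                                    colour = .data$phase,
                                    fill = .data$phase)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste("GET score:", score),
                  y = "3-D distance to turbine hub (m)",
                  colour = "Phase", fill = "Phase") +
    ggplot2::theme_minimal()
}

#' Plot a fitted-effect grid
#'
#' @param grid A tibble from [effect_grid()].
#' @param focal Name of the focal column.
#' @param panel Optional conditioning column to facet by.
#' @return A ggplot.
#' @export
plot_effect_grid <- function(grid, focal, panel = NULL) {
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data[[focal]],
                                          y = .data$fitted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = focal, y = "Fitted 3-D distance (m)") +
    ggplot2::theme_minimal()
  if (!is.null(panel)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", panel)))
  }
  p
}

#' Plot a fitted proximity model's effect for one predictor
#'
#' @param object A `ta_fit`.
#' @param focal Focal predictor; defaults to the first model term.
#' @param ... Passed to [effect_grid()].
#' @return A ggplot.
#' @method autoplot ta_fit
#' @export
autoplot.ta_fit <- function(object, focal = NULL, ...) {
  vars <- all.vars(stats::as.formula(paste("~", object$fixed)))
  if (length(vars) == 0) abort("null model has no fixed predictor to plot")
  focal <- focal %||% vars[1]
  plot_effect_grid(effect_grid(object, focal, ...), focal)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
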