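#' Plot a fitted kinetic curve over the data
#'
#' Points are the (blank-corrected) per-replicate observations; the line is
#' the fitted logistic curve, with the fitted asymptote (ultimate BOD)
#' drawn as a dashed reference.
#'
#' @param object A [fit_kinetics()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$day, y = .data$bod)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Time (days)", y = "Blank-corrected BOD (mg O2/L)",
                  title = paste0("Logistic fit (", object$model$form, ")"))
  if (!object$refused) {
    grid <- tibble(day = seq(0, max(dat$day), length.out = 200))
    grid$bod <- predict(object, grid)
    p <- p +
      ggplot2::geom_line(data = grid, colour = "#2166ac") +
      ggplot2::geom_hline(yintercept = object$coef[["bod_l"]],
                          linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot an assessment as %C+ bars over the class bands
#'
#' Horizontal bars of per-material %C+ at the assessment day over shaded
#' bands marking the four biodegradability classes (5, 20 and 60 %C+
#' boundaries).
#'
#' @param object An [assess()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bod_assessment
#' @export
autoplot.bod_assessment <- function(object, ...) {
  df <- as_tibble(object)
  bands <- tibble(
    xmin = c(-Inf, 5, 20, 60),
    xmax = c(5, 20, 60, Inf),
    category = factor(biodegradability_levels,
                      levels = biodegradability_levels)
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$category),
                       alpha = 0.15) +
    ggplot2::geom_col(ggplot2::aes(x = .data$pct_cplus,
                                   y = stats::reorder(.data$material_id,
                                                      .data$pct_cplus)),
                      width = 0.6, fill = "grey25") +
    ggplot2::scale_fill_manual(values = c(non = "#d73027", slightly = "#fee08b",
                                          moderately = "#a6d96a",
                                          readily = "#1a9850")) +
    ggplot2::labs(x = paste0("% of positive control (day ",
                             attr(object, "assessment_day"), ")"),
                  y = NULL, fill = "class")
}

#' Plot corrected BOD time courses by material
#'
#' @param corrected Output of [blank_correct()].
#' @return A ggplot object: replicate-mean corrected BOD versus time,
#'   one line per material.
#' @export
plot_bod_curves <- function(corrected) {
  means <- corrected |>
    dplyr::group_by(.data$material_id, .data$day) |>
    dplyr::summarise(bod = mean(.data$bod_corrected), .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$day, y = .data$bod,
                                      colour = .data$material_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Time (days)", y = "Blank-corrected BOD (mg O2/L)",
                  colour = "material")
}
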