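#' Plot a step curve
#'
#' Draws the right-continuous step function with optional censor marks.
#'
#' @param object A `step_curve`.
#' @param marks Optional `censor_marks` to overlay as crosses.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.step_curve <- function(object, marks = NULL, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  end_time <- attr(object, "end_time")
  df2 <- dplyr::bind_rows(df, tibble::tibble(t = end_time,
                                             S = df$S[nrow(df)]))
  p <- ggplot2::ggplot(df2, ggplot2::aes(x = .data$t, y = .data$S)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(
      x = "time",
      y = switch(curve_type(object),
                 survival = "S(t)",
                 cumulative_hazard = "H(t)",
                 cumulative_incidence = "1 - S(t)")) +
    ggplot2::theme_minimal()
  if (!is.null(marks) && nrow(marks) > 0) {
    p <- p + ggplot2::geom_point(
      data = tibble::as_tibble(as.data.frame(marks)),
      ggplot2::aes(x = .data$t, y = .data$S), shape = 3, size = 2)
  }
  p
}

#' Plot extracted figure segments in device space
#'
#' Quick visual audit of what the extractor found: segments as lines, dots
#' as points, coloured by path.
#'
#' @param object A `ps_segments` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ps_segments <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      data = df[!df$is_dot, , drop = FALSE],
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = factor(.data$path_id))) +
    ggplot2::geom_point(
      data = df[df$is_dot, , drop = FALSE],
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   colour = factor(.data$path_id)), size = 0.8) +
    ggplot2::labs(x = "device x (points)", y = "device y (points)",
                  colour = "path") +
    ggplot2::theme_minimal()
}

#' Plot a recovered risk-set table
#'
#' The diagnostic view used to spot tied-event multiplicities: inferred
#' numbers at risk against event time, with point size showing the event
#' count.
#'
#' @param object A `risk_set_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_set_table <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$n)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$d), alpha = 0.8) +
    ggplot2::geom_line(linetype = 3, linewidth = 0.3) +
    ggplot2::scale_size_continuous(range = c(1.5, 3.5),
                                   breaks = function(x) {
                                     seq(ceiling(x[1]), floor(x[2]))
                                   }) +
    ggplot2::labs(x = "event time", y = "number at risk", size = "events") +
    ggplot2::theme_minimal()
}
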