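# ggplot2 figure builders for the main result types.

#' Plot method for `ll_sweep` objects
#' @param object The object to plot.
#' @param ... Unused.
#' @method autoplot ll_sweep
#' @export
autoplot.ll_sweep <- function(object, ...) {
  bp <- best_per_size(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$mean_r2)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.45, size = 1.6) +
    ggplot2::geom_line(data = bp, colour = "#d95f02", linewidth = 0.8) +
    ggplot2::geom_point(data = bp, colour = "#d95f02", size = 2.6) +
    ggplot2::scale_x_continuous(breaks = 1:6) +
    ggplot2::labs(x = "Number of sensor locations",
                  y = expression(Mean~r^2~across~participants),
                  title = "Algorithm accuracy vs. number of sensor locations") +
    ggplot2::theme_minimal()
}

#' Plot method for `ll_loso` objects
#' @param object The object to plot.
#' @param ... Unused.
#' @method autoplot ll_loso
#' @export
autoplot.ll_loso <- function(object, max_points = 20000, ...) {
  p <- object$predictions
  if (nrow(p) > max_points) p <- p[seq(1, nrow(p), length.out = max_points), ]
  lim <- range(c(p$target, p$prediction))
  ggplot2::ggplot(p, ggplot2::aes(x = .data$target, y = .data$prediction)) +
    ggplot2::geom_point(alpha = 0.08, size = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "#d95f02") +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(x = "Lab-based lumbar moment (BW x BH)",
                  y = "Wearable estimate (BW x BH)",
                  title = "Held-out wearable estimates vs. ground truth") +
    ggplot2::theme_minimal()
}

#' Plot method for `ll_importance` objects
#' @param object The object to plot.
#' @param ... Unused.
#' @method autoplot ll_importance
#' @export
autoplot.ll_importance <- function(object, top = 15, ...) {
  d <- head(object, top)
  d$channel <- factor(d$channel, levels = rev(d$channel))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_r2, y = .data$channel)) +
    ggplot2::geom_col(fill = "#1b9e77") +
    ggplot2::geom_errorbar(ggplot2::aes(xmin = .data$delta_r2 - .data$delta_r2_sd,
                                        xmax = .data$delta_r2 + .data$delta_r2_sd),
                           width = 0.25, linewidth = 0.3) +
    ggplot2::labs(x = expression(Delta~r^2~(permutation~importance)),
                  y = NULL, title = "Signal importance") +
    ggplot2::theme_minimal()
}

#' Overlay ground-truth and estimated moment time series for one task
#'
#' @param predictions `ll_loso$predictions` (BW x BH units).
#' @param participant,task Identifiers selecting the trial to plot.
#' @return A ggplot object.
#' @export
plot_moment_overlay <- function(predictions, participant, task) {
  d <- dplyr::filter(predictions, .data$participant_id == participant,
                     .data$task_id == task)
  if (nrow(d) == 0) abort("no samples for that participant/task.")
  long <- tidyr::pivot_longer(d, c("target", "prediction"),
                              names_to = "series", values_to = "moment")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$moment,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(target = "#1b9e77",
                                            prediction = "#d95f02"),
                                 labels = c(target = "lab truth",
                                            prediction = "wearable estimate")) +
    ggplot2::labs(x = "Time (s)", y = "Lumbar extension moment (BW x BH)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
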