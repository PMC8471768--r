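#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the stopping and bifurcation traces of a track
#'
#' Two stacked panels: the summed candidate likelihood tau per step with the
#' stopping threshold, and the inter-cluster angle theta per step with the
#' bifurcation threshold. Peaks in theta mark bifurcation candidates; the
#' collapse of tau marks the distal end.
#'
#' @param object a `track_result`.
#' @param cfg the [tracker_config()] used (for the threshold lines).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.track_result <- function(object, cfg = tracker_config(), ...) {
  tr <- dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(object$tau_trace, value = "tau"),
                  trace = "tau (summed likelihood)",
                  threshold = cfg$stop_threshold),
    dplyr::mutate(dplyr::rename(object$theta_trace, value = "theta"),
                  trace = "theta (cluster angle, deg)",
                  threshold = cfg$branch_angle))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed", colour = "red3") +
    ggplot2::facet_wrap(~trace, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "tracking step", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a learned direction-change prior
#'
#' @param object a `direction_prior`.
#' @param ... unused.
#' @return a ggplot of per-bin probability over angle.
#' @export
autoplot.direction_prior <- function(object, ...) {
  df <- tibble::tibble(
    angle = (object$breaks[-length(object$breaks)] + object$breaks[-1]) / 2,
    prob = object$prob)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$prob)) +
    ggplot2::geom_col(width = diff(object$breaks[1:2]) * 0.9) +
    ggplot2::labs(x = "direction change per step (deg)", y = "probability") +
    ggplot2::theme_minimal()
}

#' Plot evaluation marks as a 2D projection
#'
#' Projects reference and method points onto a coordinate plane and colours
#' them by their TPR/FN/TPM/FP mark.
#'
#' @param object an `eval_report`.
#' @param plane which coordinate plane to project onto.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.eval_report <- function(object, plane = c("xz", "xy", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  df <- tidy.eval_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                   colour = .data$mark, shape = .data$set)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(ax[1], "(mm)"), y = paste(ax[2], "(mm)")) +
    ggplot2::theme_minimal()
}
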