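#' Plot a turn-angle distribution
#'
#' @param x A `turn_distribution` (or a list of them, named by group).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_turn_distribution <- function(x, ...) {
  d <- if (inherits(x, "turn_distribution")) {
    mutate(as_tibble(x), group = "all")
  } else {
    purrr::imap_dfr(x, function(td, nm) mutate(as_tibble(td), group = nm))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_mid, y = .data$probability,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "turn angle (deg, + = leftward)", y = "probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a binned performance curve (time or trial ordinal)
#'
#' @param curve Output of [performance_vs_time()] or
#'   [performance_vs_trial()].
#' @param x_lab Axis label.
#' @return A ggplot object.
#' @export
plot_performance_curve <- function(curve, x_lab = "time since motion onset (s)") {
  s <- curve$summary
  xvar <- if ("t_mid" %in% names(s)) "t_mid" else "set"
  ggplot2::ggplot(s, ggplot2::aes(x = .data[[xvar]], y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = x_lab, y = "proportion correct") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-trial index values across units
#'
#' @param idx Tibble with `unit_id`, a trial/pair column, and a value column
#'   (responsiveness or DSI).
#' @param value Column to plot. Default `"responsiveness"`.
#' @param trial_col Trial column. Default `"trial"`.
#' @return A ggplot object.
#' @export
plot_index_heatmap <- function(idx, value = "responsiveness",
                               trial_col = "trial") {
  ggplot2::ggplot(idx, ggplot2::aes(x = .data[[trial_col]],
                                    y = .data$unit_id,
                                    fill = .data[[value]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "goldenrod", mid = "white",
                                  high = "salmon", limits = c(-1, 1)) +
    ggplot2::labs(x = trial_col, y = "unit", fill = value) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot an exponential bout-rate recovery fit
#'
#' @param object An `exp_recovery_fit`.
#' @param times,rates The data that were fitted (optional; curve only if
#'   absent).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exp_recovery_fit <- function(object, times = NULL, rates = NULL,
                                      ...) {
  stopifnot(object$converged)
  tmax <- if (is.null(times)) object$t0 + 6 * object$tau_min else max(times)
  grid <- seq(min(0, object$t0), tmax, length.out = 200)
  pred <- ifelse(grid >= object$t0,
                 object$r_inf * (1 - exp(-(grid - object$t0) /
                                           object$tau_min)), 0)
  p <- ggplot2::ggplot(tibble(t = grid, r = pred),
                       ggplot2::aes(.data$t, .data$r)) +
    ggplot2::geom_line(colour = "deeppink") +
    ggplot2::labs(x = "time since washout (min)", y = "bout rate (Hz)") +
    ggplot2::theme_minimal()
  if (!is.null(times)) {
    p <- p + ggplot2::geom_point(data = tibble(t = times, r = rates))
  }
  p
}

#' Autoplot a logistic recovery fit
#'
#' @param object A `logistic_fit`.
#' @param times,values Fitted data (optional).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.logistic_fit <- function(object, times = NULL, values = NULL, ...) {
  tmin <- if (is.null(times)) object$x0_min - 5 * object$k_min
          else min(times)
  tmax <- if (is.null(times)) object$x0_min + 5 * object$k_min
          else max(times)
  grid <- seq(tmin, tmax, length.out = 200)
  pred <- object$amplitude *
    stats::plogis((grid - object$x0_min) / object$k_min)
  p <- ggplot2::ggplot(tibble(t = grid, v = pred),
                       ggplot2::aes(.data$t, .data$v)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$x0_min, linetype = "dotted") +
    ggplot2::labs(x = "washout time (min)", y = "response") +
    ggplot2::theme_minimal()
  if (!is.null(times)) {
    p <- p + ggplot2::geom_point(data = tibble(t = times, v = values))
  }
  p
}
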