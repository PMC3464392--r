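# ggplot2 displays for the result types.

#' @export
autoplot.compartment_trace <- function(object, ...) {
  dat <- tidyr::pivot_longer(as_tibble(object),
                             c("vascular_mean", "tissue_mean"),
                             names_to = "compartment", values_to = "intensity")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s / 60,
                                    y = .data$intensity,
                                    colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "ep_time") / 60,
                        linetype = "dashed") +
    ggplot2::labs(x = "time after EP (min)", y = "mean intensity",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fill_kinetics <- function(object, ...) {
  dat <- tidy(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_after_injection_s / 60,
                                         y = .data$fill_pct)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$completion_threshold,
                        linetype = "dotted") +
    ggplot2::labs(x = "time after injection (min)",
                  y = expression("vascular intensity (% of " * I[max] * ")")) +
    ggplot2::theme_minimal()
  if (object$completion_reached) {
    p <- p + ggplot2::geom_vline(xintercept = object$completion_s / 60,
                                 linetype = "dashed")
  }
  p
}

#' @export
autoplot.leakage_kinetics <- function(object, fit = NULL, ...) {
  dat <- tidy(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s / 60,
                                         y = .data$delta_rel)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time after EP (min)",
                  y = "relative variation of tissue intensity") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    t0 <- fit$reference_time
    pred <- tibble(
      time_s = dat$time_s[dat$time_s >= t0],
    )
    pred$fit <- fit$slope_per_min *
      (pmin(pred$time_s, fit$breakpoint_s) - t0) / 60
    p <- p + ggplot2::geom_line(data = pred,
                                ggplot2::aes(y = .data$fit),
                                colour = "red")
  }
  p
}

#' @export
autoplot.delay_sweep <- function(object, metric = c("completion_min",
                                                    "leak_rate_per_min"),
                                 ...) {
  metric <- match.arg(metric)
  dat <- object$data
  dat$condition <- factor(dat$condition,
                          levels = c("control", as.character(object$delays_min)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$condition, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, size = 1) +
    ggplot2::labs(x = "injection delay after EP (min)",
                  y = if (metric == "completion_min") "completion time (min)"
                      else "leakage rate (1/min)") +
    ggplot2::theme_minimal()
}

#' Plot normalized diameter time courses by group
#'
#' @param data Tidy tibble as returned by [simulate_vessel_cohort()]
#'   (columns `condition`, `animal`, `time_s`, `value`).
#' @return A ggplot.
#' @export
plot_diameter_groups <- function(data) {
  ggplot2::ggplot(as_tibble(data),
                  ggplot2::aes(x = .data$time_s / 60, y = .data$value,
                               colour = .data$condition,
                               group = interaction(.data$condition,
                                                   .data$animal))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time after EP (min)", y = "normalized diameter",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
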