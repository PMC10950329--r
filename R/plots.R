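#' Plot an averaged normalized trace
#'
#' Mean norm. dF with a +/- SEM ribbon; if a [fit_decay()] result is given,
#' the fitted mono-exponential is overlaid from the peak onward.
#'
#' @param object An `avg_trace`.
#' @param fit Optional `decay_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot avg_trace
#' @export
autoplot.avg_trace <- function(object, fit = NULL, ...) {
  dat <- as_tibble(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s, y = .data$norm_df)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$norm_df - .data$sem,
                                      ymax = .data$norm_df + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(paste("norm. ", Delta, "F")))
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(
      data = fit$data,
      ggplot2::aes(x = .data$time_s, y = .data$fitted),
      colour = "red", linetype = 2)
  }
  p
}

#' Plot a constrained decay fit
#'
#' Post-peak data points with the fitted exp(-t'/tau) curve.
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$t_prime, y = .data$norm_df)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time since peak (s)",
                  y = expression(paste("norm. ", Delta, "F")),
                  title = sprintf("tau = %.1f s", object$tau))
}

#' Plot averaged synaptic localization profiles
#'
#' Mean max-normalized intensity +/- SEM per channel against the signed
#' position along the synaptic axis (0 nm at the reference maximum,
#' postsynapse at negative positions).
#'
#' @param object A `localization_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot localization_profile
#' @export
autoplot.localization_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position_nm, y = .data$mean_norm,
                               colour = .data$channel,
                               fill = .data$channel)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_norm - .data$sem,
                                      ymax = .data$mean_norm + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "position relative to reference maximum (nm)",
                  y = "normalized intensity")
}
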