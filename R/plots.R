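# ggplot2 graphics for the main result types

#' Plot viscosity-versus-shear-rate curves
#'
#' Log-log curves of effective viscosity for one or more blood conditions,
#' the standard way shear-thinning rheology is displayed.
#'
#' @param conditions Character vector of condition names and/or
#'   `rheology_params` objects (default: all four built-ins).
#' @param shear_rates Shear-rate grid (1/s).
#' @return A ggplot object.
#' @examples
#' plot_viscosity_curves()
#' @export
plot_viscosity_curves <- function(conditions = c("anemic", "diabetic",
                                                 "healthy1", "healthy2"),
                                  shear_rates = 10^seq(-2, 4, length.out = 161)) {
  if (!is.list(conditions)) conditions <- as.list(conditions)
  dat <- purrr::map_dfr(conditions, viscosity_curve, shear_rates = shear_rates)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$shear_rate, y = .data$mu_eff,
                                    colour = .data$condition)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(paste("shear rate ", dot(gamma), " (", s^-1, ")")),
                  y = expression(paste(mu[eff], " (Pa s)")),
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' @method autoplot waveform_params
#' @export
autoplot.waveform_params <- function(object, dt = object$period / 500,
                                     n_cycles = 2, ...) {
  tr <- waveform_trace(object, dt = dt, n_cycles = n_cycles)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (s)", y = "inlet velocity (m/s)") +
    ggplot2::theme_minimal()
}

#' @method autoplot tube_fit
#' @export
autoplot.tube_fit <- function(object, phases = c(0.05, 0.109, 0.218, 0.35), ...) {
  s <- tidy(object)
  t0 <- min(s$t) - object$dt
  want <- t0 + phases
  prof <- object$profiles
  sel <- purrr::map_dfr(want, function(tt) {
    near <- prof$t[which.min(abs(prof$t - tt))]
    dplyr::filter(prof, .data$t == near)
  })
  sel$phase <- sprintf("tau = %.3f s", sel$t - t0)
  p1 <- ggplot2::ggplot(sel, ggplot2::aes(x = .data$r, y = .data$u,
                                          colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (m)", y = "u (m/s)", colour = NULL,
                  title = sprintf("radial profiles (%s)", object$rheology$name)) +
    ggplot2::theme_minimal()
  p1
}

#' @method autoplot arch_report
#' @export
autoplot.arch_report <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$traces,
                            c("ubar", "wss", "P_wall"),
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = "t (s)", y = NULL, colour = "branch",
                  title = sprintf("final cycle, %s", object$condition)) +
    ggplot2::theme_minimal()
}

#' @method autoplot severity_report
#' @export
autoplot.severity_report <- function(object, ...) {
  cols <- c(green = "#2e7d32", yellow = "#f9a825", red = "#c62828")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$metric, y = 1,
                                       fill = .data$category)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 3))) +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "illustrative severity classification") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
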