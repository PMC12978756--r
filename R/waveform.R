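#' Pulsatile cardiac inlet waveform parameters
#'
#' The inlet velocity is a periodic piecewise function of in-cycle time
#' \eqn{\tau}: a sinusoidal systolic segment
#' \eqn{A \sin[\omega(\tau + t_0)]} for \eqn{\tau \in (0, t_s]} followed by
#' a constant diastolic plateau on \eqn{(t_s, T]}. The defaults (period
#' 0.5 s, i.e. 120 beats per minute; systole ending at 0.218 s; amplitude
#' 0.5 m/s; plateau 0.1 m/s; phase offset 0.016 s; angular factor 4\eqn{\pi}
#' rad/s) make the waveform nearly continuous at both segment junctions.
#'
#' @param period Cardiac cycle duration (s).
#' @param systole_end End of the sinusoidal segment within the cycle (s),
#'   must lie in `(0, period)`.
#' @param amplitude Sinusoid amplitude (m/s), non-negative. `amplitude =
#'   0` degenerates to a constant waveform at the diastolic level — the
#'   steady-flow limit used by the steady verification cases.
#' @param diastolic_level Plateau velocity (m/s), non-negative.
#' @param phase_offset Phase shift of the sinusoid (s).
#' @param angular_factor Angular frequency of the sinusoid (rad/s).
#' @return An object of class `waveform_params`.
#' @examples
#' wf <- waveform_params()
#' inlet_velocity(c(0.109, 0.35), wf)
#' @export
waveform_params <- function(period = 0.5, systole_end = 0.218,
                            amplitude = 0.5, diastolic_level = 0.1,
                            phase_offset = 0.016, angular_factor = 4 * pi) {
  check_positive(period, "period")
  check_scalar(systole_end, "systole_end")
  check_non_negative(amplitude, "amplitude")
  check_non_negative(diastolic_level, "diastolic_level")
  check_scalar(phase_offset, "phase_offset")
  check_positive(angular_factor, "angular_factor")
  if (systole_end <= 0 || systole_end >= period) {
    abort_invalid("`systole_end` must lie strictly inside (0, period).")
  }
  structure(
    list(period = period, systole_end = systole_end, amplitude = amplitude,
         diastolic_level = diastolic_level, phase_offset = phase_offset,
         angular_factor = angular_factor),
    class = "waveform_params"
  )
}

#' @export
print.waveform_params <- function(x, ...) {
  cat(sprintf(
    "<waveform_params>\n  period %.4g s, systole (0, %.4g], amplitude %.4g m/s\n  plateau %.4g m/s, phase offset %.4g s, angular factor %.4g rad/s\n",
    x$period, x$systole_end, x$amplitude, x$diastolic_level,
    x$phase_offset, x$angular_factor))
  invisible(x)
}

#' Inlet velocity at a time point
#'
#' Evaluates the pulsatile inlet waveform, extended periodically to all real
#' times (negative included). In-cycle time \eqn{\tau = t - nT} uses the
#' half-open intervals \eqn{(0, t_s]} (sinusoid) and \eqn{(t_s, T]}
#' (plateau); \eqn{\tau = 0} therefore takes the plateau value, matching the
#' diastolic end of the previous cycle.
#'
#' @param t Time(s) in seconds, any finite real.
#' @param params A [waveform_params()] object.
#' @return Velocity in m/s, same length as `t`.
#' @examples
#' inlet_velocity(0.35)                     # diastolic plateau: 0.1 m/s
#' inlet_velocity(0.85) == inlet_velocity(0.35)  # periodicity
#' @export
inlet_velocity <- function(t, params = waveform_params()) {
  check_finite(t, "t")
  if (params$amplitude == 0) return(rep(params$diastolic_level, length(t)))
  tau <- t - params$period * floor(t / params$period)
  v <- rep(params$diastolic_level, length(t))
  sys <- tau > 0 & tau <= params$systole_end
  v[sys] <- params$amplitude *
    sin(params$angular_factor * (tau[sys] + params$phase_offset))
  v
}

#' Time-averaged inlet velocity over one cycle
#'
#' Closed-form average of [inlet_velocity()] over one period: the exact
#' integral of the sinusoidal segment plus the plateau contribution. For the
#' default constants this is about 0.2123 m/s; it feeds the Windkessel
#' total-resistance estimate (mean pressure / mean flow).
#'
#' @inheritParams inlet_velocity
#' @return Mean velocity in m/s.
#' @examples
#' mean_inlet_velocity()
#' @export
mean_inlet_velocity <- function(params = waveform_params()) {
  if (params$amplitude == 0) return(params$diastolic_level)
  w <- params$angular_factor
  sin_part <- params$amplitude / w *
    (cos(w * params$phase_offset) -
       cos(w * (params$systole_end + params$phase_offset)))
  plateau_part <- params$diastolic_level * (params$period - params$systole_end)
  (sin_part + plateau_part) / params$period
}

#' Uniformly sampled waveform trace
#'
#' Samples the inlet waveform at `t = dt, 2 dt, ..., n_cycles * period`
#' (the sample at `t = 0` belongs to the previous cycle's plateau and is
#' omitted so that each cycle contributes the same number of samples).
#'
#' @inheritParams inlet_velocity
#' @param dt Sampling interval (s), `0 < dt < period`.
#' @param n_cycles Number of cardiac cycles to cover (integer >= 1).
#' @return A tibble with columns `t` (s) and `v` (m/s).
#' @examples
#' waveform_trace(dt = 0.005, n_cycles = 2)
#' @export
waveform_trace <- function(params = waveform_params(), dt = params$period / 100,
                           n_cycles = 1L) {
  check_positive(dt, "dt")
  if (dt >= params$period) abort_invalid("`dt` must be smaller than the period.")
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles < 1) {
    abort_invalid("`n_cycles` must be a positive integer.")
  }
  spc <- params$period / dt
  if (abs(spc - round(spc)) < 1e-9 * spc) {
    # dt divides the period: evaluate one cycle and tile it, so consecutive
    # cycles are identical samplewise (no floating-point drift in tau)
    spc <- round(spc)
    tau <- seq_len(spc) * dt
    v <- rep(inlet_velocity(tau, params), times = n_cycles)
    t <- rep(tau, times = n_cycles) +
      params$period * rep(seq_len(n_cycles) - 1, each = spc)
  } else {
    t <- seq_len(round(n_cycles * params$period / dt)) * dt
    v <- inlet_velocity(t, params)
  }
  tibble::tibble(t = t, v = v)
}
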