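#' Three-element Windkessel (RCR) parameters
#'
#' Proximal resistance `R1`, distal resistance `R2` and compliance `C` of
#' the lumped outlet model. The outlet pressure is
#' \eqn{P(t) = P_c(t) + R_1 Q(t)}, where the capacitor pressure obeys
#' \eqn{C\,dP_c/dt = Q - P_c / R_2}.
#'
#' @param R1 Proximal resistance (Pa s/m^3), positive.
#' @param R2 Distal resistance (Pa s/m^3), positive.
#' @param C Compliance (m^3/Pa), positive.
#' @return An object of class `windkessel_params`.
#' @seealso [estimate_windkessel()] for the mean-haemodynamics estimate.
#' @export
windkessel_params <- function(R1, R2, C) {
  check_positive(R1, "R1"); check_positive(R2, "R2"); check_positive(C, "C")
  structure(list(R1 = R1, R2 = R2, C = C), class = "windkessel_params")
}

#' @export
print.windkessel_params <- function(x, ...) {
  cat(sprintf(
    "<windkessel_params>\n  R1 = %.6g Pa s/m^3, R2 = %.6g Pa s/m^3, C = %.6g m^3/Pa\n  (R1/Rtot = %.4g, tau = R2 C = %.4g s)\n",
    x$R1, x$R2, x$C, x$R1 / (x$R1 + x$R2), x$R2 * x$C))
  invisible(x)
}

#' Estimate Windkessel parameters from mean haemodynamics
#'
#' Splits the total resistance `Rtot = mean_pressure / mean_flow` into a
#' 5 percent proximal and 95 percent distal part, and sets the compliance
#' from the diastolic decay constant: `R1 = 0.05 Rtot`, `R2 = 0.95 Rtot`,
#' `C = tau / R2`. By construction `R1 / Rtot = 0.05` and `C * R2 = tau`
#' hold exactly.
#'
#' @param mean_pressure Target mean outlet pressure (Pa), positive; the
#'   default 13332 Pa is roughly 100 mmHg.
#' @param mean_flow Mean branch flow (m^3/s), positive.
#' @param tau Diastolic decay constant (s), default 1.0.
#' @return A [windkessel_params()] object.
#' @examples
#' estimate_windkessel(13332, 1e-4, tau = 1)
#' @export
estimate_windkessel <- function(mean_pressure = 13332, mean_flow, tau = 1.0) {
  check_positive(mean_pressure, "mean_pressure")
  check_positive(mean_flow, "mean_flow")
  check_positive(tau, "tau")
  Rtot <- mean_pressure / mean_flow
  R2 <- 0.95 * Rtot
  windkessel_params(R1 = 0.05 * Rtot, R2 = R2, C = tau / R2)
}

#' Windkessel state
#'
#' A consistent snapshot of the RCR outlet: capacitor pressure `Pc`, last
#' flow `Q`, time `t`, and the derived outlet pressure `P = Pc + R1 Q`.
#'
#' @param Pc Capacitor pressure (Pa).
#' @param Q Flow through the outlet (m^3/s).
#' @param t Time (s).
#' @param params A [windkessel_params()] object (supplies `R1`).
#' @return An object of class `windkessel_state`.
#' @export
windkessel_state <- function(Pc, Q = 0, t = 0, params) {
  check_scalar(Pc, "Pc"); check_scalar(Q, "Q"); check_scalar(t, "t")
  if (!inherits(params, "windkessel_params")) {
    abort_invalid("`params` must be a windkessel_params object.")
  }
  structure(list(P = Pc + params$R1 * Q, Pc = Pc, Q = Q, t = t),
            class = "windkessel_state")
}

#' One backward-Euler Windkessel step
#'
#' Advances the RCR outlet pressure by one implicit step. With
#' \eqn{\beta = R_2 C / \Delta t} the capacitor update is
#' \deqn{P_c^{n+1} = \frac{\beta P_c^n + R_2 Q^{n+1}}{1 + \beta},}
#' algebraically identical to the outlet-pressure form
#' \deqn{P^{n+1} = \frac{\beta P^n + Q^{n+1}(R_2 + R_1 + R_1\beta)
#'       - R_1 \beta Q^n}{1 + \beta}.}
#' Both forms are implemented (`form`) and agree to round-off; the update is
#' the exact backward-Euler discretization of the RCR ODE and is
#' unconditionally stable (\eqn{\beta/(1+\beta) < 1} for any `dt`).
#'
#' Note on \eqn{\beta}: the product form \eqn{R_2 C \Delta t} sometimes seen
#' in print is dimensionally inconsistent; the dimensionless
#' \eqn{\beta = R_2 C / \Delta t} is used here, which is what makes the
#' update equivalent to backward Euler.
#'
#' @param state A [windkessel_state()].
#' @param Q_new Flow at the new time level (m^3/s).
#' @param params A [windkessel_params()] object.
#' @param dt Time step (s), positive.
#' @param form `"Pc"` (default) or `"P"`: which algebraic form to step.
#' @return The updated `windkessel_state` at `t + dt`.
#' @export
windkessel_step <- function(state, Q_new, params, dt, form = c("Pc", "P")) {
  form <- match.arg(form)
  if (!inherits(state, "windkessel_state")) {
    abort_invalid("`state` must be a windkessel_state object.")
  }
  check_scalar(Q_new, "Q_new")
  check_positive(dt, "dt")
  beta <- params$R2 * params$C / dt
  if (form == "Pc") {
    Pc_new <- (beta * state$Pc + params$R2 * Q_new) / (1 + beta)
    P_new <- Pc_new + params$R1 * Q_new
  } else {
    P_new <- (beta * state$P +
                Q_new * (params$R2 + params$R1 + params$R1 * beta) -
                params$R1 * beta * state$Q) / (1 + beta)
    Pc_new <- P_new - params$R1 * Q_new
  }
  structure(list(P = P_new, Pc = Pc_new, Q = Q_new, t = state$t + dt),
            class = "windkessel_state")
}

#' Simulate a Windkessel outlet over a flow series
#'
#' Applies [windkessel_step()] sequentially over a uniformly sampled flow
#' series. The linear recursion is evaluated with `stats::filter`
#' (recursive form), which is arithmetic-identical to the explicit loop.
#' After several periods of a periodic flow the pressure trace becomes
#' cycle-periodic and its cycle mean approaches `(R1 + R2) * mean(Q)`.
#'
#' @param flow A data frame with columns `t` (s, strictly increasing,
#'   uniform spacing) and `Q` (m^3/s). The first row is taken as the
#'   initial time level.
#' @param params A [windkessel_params()] object.
#' @param Pc0 Initial capacitor pressure (Pa); defaults to the steady value
#'   `R2 * Q[1]` unless supplied.
#' @param form `"Pc"` or `"P"`; see [windkessel_step()].
#' @return A tibble with columns `t`, `Q`, `Pc`, `P`.
#' @examples
#' wk <- estimate_windkessel(13332, 1e-4)
#' fl <- tibble::tibble(t = seq(0, 2, by = 0.005),
#'                      Q = 1e-4 * (1 + 0.3 * sin(4 * pi * t)))
#' head(windkessel_simulate(fl, wk))
#' @export
windkessel_simulate <- function(flow, params, Pc0 = NULL, form = c("Pc", "P")) {
  form <- match.arg(form)
  if (!is.data.frame(flow) || !all(c("t", "Q") %in% names(flow))) {
    abort_invalid("`flow` must be a data frame with columns `t` and `Q`.")
  }
  t <- flow$t; Q <- flow$Q
  check_finite(t, "flow$t"); check_finite(Q, "flow$Q")
  if (length(t) < 2) abort_invalid("`flow` needs at least two samples.")
  dts <- diff(t)
  if (any(dts <= 0)) abort_invalid("`flow$t` must be strictly increasing.")
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-8 * dt)) {
    abort_invalid("`flow$t` must be uniformly spaced.")
  }
  beta <- params$R2 * params$C / dt
  a <- beta / (1 + beta)
  n <- length(t)
  Pc0 <- Pc0 %||% (params$R2 * Q[1])
  check_scalar(Pc0, "Pc0")
  if (form == "Pc") {
    b <- params$R2 * Q[-1] / (1 + beta)
    Pc <- c(Pc0, as.numeric(stats::filter(b, a, method = "recursive",
                                          init = Pc0)))
    P <- Pc + params$R1 * Q
  } else {
    P0 <- Pc0 + params$R1 * Q[1]
    b <- (Q[-1] * (params$R2 + params$R1 + params$R1 * beta) -
            params$R1 * beta * Q[-n]) / (1 + beta)
    P <- c(P0, as.numeric(stats::filter(b, a, method = "recursive",
                                        init = P0)))
    Pc <- P - params$R1 * Q
  }
  tibble::tibble(t = t, Q = Q, Pc = Pc, P = P)
}
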