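# Shared oracles for the verification suite. These deliberately take an
# independent route from the implementation they check.

# constant-viscosity parameter set (degenerate Carreau: both plateaus equal)
newtonian_params <- function(mu = 0.0035, density = 1060) {
  rheology_params("newtonian", k = 0.5, lambda = 1, mu0 = mu, mu_inf = mu,
                  density = density)
}

# direct textbook evaluation of the Carreau law (plain `^`, no exp/log
# rewrite, no clamping) — the independent route for the 12-digit check
carreau_direct <- function(g, p) {
  p$mu_inf + (p$mu0 - p$mu_inf) * (1 + (p$lambda * g)^2)^((p$k - 1) / 2)
}

# space-time relative L2 error of the pulsatile solver against the analytic
# Womersley solution (dpdx-driven, initialized on the analytic state)
womersley_solver_error <- function(ref, nr, dt, n_cycles = 1) {
  r <- seq(0, ref$radius, length.out = nr)
  fit <- solve_pulsatile_tube(
    ref$radius, newtonian_params(ref$viscosity, ref$density),
    waveform_params(period = 2 * pi / ref$omega),
    nr = nr, dt = dt, n_cycles = n_cycles, mode = "dpdx",
    dpdx_fun = function(t) womersley_dpdx(ref, t),
    init = womersley_profile(ref, r, 0))
  num <- den <- 0
  wss_err <- 0
  mu <- ref$viscosity
  for (d in split(fit$profiles, fit$profiles$t)) {
    tt <- d$t[1]
    ua <- womersley_profile(ref, d$r, tt)
    num <- num + sum((d$u - ua)^2)
    den <- den + sum(ua^2)
    # analytic wall gradient by one-sided difference of the analytic field
    h <- ref$radius * 1e-7
    uw <- womersley_profile(ref, ref$radius - c(0, h, 2 * h), tt)
    tau_exact <- mu * abs((3 * uw[1] - 4 * uw[2] + uw[3]) / (-2 * h))
    tau_num <- wall_shear_stress(radial_profile(d$r, d$u),
                                 newtonian_params(mu, ref$density))
    wss_err <- max(wss_err, abs(tau_num - tau_exact))
  }
  list(l2 = sqrt(num / den), wss_abs = wss_err,
       wss_rel = wss_err / (max(abs(fit$summary$wss))))
}

# reference RCR solution by adaptive ODE integration (deSolve), for the
# first-order-convergence check of the backward-Euler update
rcr_ode_oracle <- function(params, Q_fun, Pc0, times) {
  deSolve::lsoda(
    y = c(Pc = Pc0), times = times,
    func = function(t, y, parms) {
      list((Q_fun(t) - y[1] / params$R2) / params$C)
    },
    rtol = 1e-10, atol = 1e-8)[, "Pc"]
}

severity_level <- function(cat) c(green = 1, yellow = 2, red = 3)[[cat]]
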