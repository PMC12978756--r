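# Radially resolved pulsatile tube flow with shear-rate-dependent viscosity.
#
# The three-dimensional arch is reduced to fully developed axisymmetric flow
# in a rigid circular tube, where the convective term vanishes identically
# and the axial momentum balance becomes
#
#   rho du/dt = -dp/dx + (1/r) d/dr ( r mu(|du/dr|) du/dr ),   u(R) = 0.
#
# Discretization: node-centred uniform radial grid, conservative
# finite-volume fluxes r_{i+1/2} mu_{i+1/2} (u_{i+1} - u_i)/h (exact for a
# parabolic profile), regularized axis limit at r = 0, backward Euler in
# time, Picard (lagged-viscosity) iteration for the nonlinearity. In the
# default mode the cross-section mean velocity is prescribed (the cardiac
# waveform) and the uniform axial pressure gradient is the extra unknown of
# a bordered tridiagonal system, solved by block elimination with two
# Thomas sweeps.

#' Uniform radial grid for the tube solver
#'
#' @param radius Tube radius (m), positive.
#' @param nr Number of radial nodes including the axis and the wall
#'   (integer >= 16).
#' @return A list with `radius`, `nr`, node radii `r` (from 0 to `radius`)
#'   and spacing `h`.
#' @export
radial_grid <- function(radius, nr = 101) {
  check_positive(radius, "radius")
  if (!is.numeric(nr) || length(nr) != 1 || nr < 16 || nr != round(nr)) {
    abort_invalid("`nr` must be an integer >= 16.")
  }
  r <- seq(0, radius, length.out = nr)
  list(radius = radius, nr = as.integer(nr), r = r, h = r[2] - r[1])
}

#' Radial velocity profile
#'
#' A snapshot of the reduced flow state: axial velocity on a radial grid at
#' one time level, with the driving pressure gradient attached.
#'
#' @param r Node radii (m), strictly increasing from 0 to the wall.
#' @param u Axial velocity at the nodes (m/s); the wall value must be 0
#'   (no-slip).
#' @param t Time (s) of the snapshot.
#' @param dpdx Axial pressure gradient (Pa/m) driving the snapshot.
#' @return A tibble with columns `r`, `u` and attributes `t`, `dpdx`,
#'   class `radial_profile`.
#' @export
radial_profile <- function(r, u, t = NA_real_, dpdx = NA_real_) {
  check_finite(r, "r"); check_finite(u, "u")
  if (length(r) != length(u)) abort_invalid("`r` and `u` must match in length.")
  if (is.unsorted(r, strictly = TRUE)) {
    abort_invalid("`r` must be strictly increasing.")
  }
  if (abs(u[length(u)]) > 1e-12 * max(abs(u), 1e-300)) {
    abort_invalid("no-slip violated: wall velocity must be zero.")
  }
  out <- tibble::tibble(r = as.double(r), u = as.double(u))
  attr(out, "t") <- t
  attr(out, "dpdx") <- dpdx
  class(out) <- c("radial_profile", class(out))
  out
}

# trapezoidal weights for the cross-section mean (2/R^2) int_0^R u r dr
mean_weights <- function(grid) {
  w <- rep(grid$h, grid$nr)
  w[c(1, grid$nr)] <- grid$h / 2
  2 * w * grid$r / grid$radius^2
}

# Thomas algorithm for a tridiagonal system with multiple right-hand sides.
# lower[i] multiplies x[i-1] in row i (lower[1] unused), upper[i] multiplies
# x[i+1] (upper[n] unused).
thomas_solve <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  rhs <- as.matrix(rhs)
  cp <- numeric(n)
  dp <- matrix(0, n, ncol(rhs))
  cp[1] <- upper[1] / diag[1]
  dp[1, ] <- rhs[1, ] / diag[1]
  for (i in 2:n) {
    m <- diag[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / m
    dp[i, ] <- (rhs[i, ] - lower[i] * dp[i - 1, ]) / m
  }
  x <- dp
  for (i in (n - 1):1) x[i, ] <- dp[i, ] - cp[i] * x[i + 1, ]
  x
}

# Assemble the tridiagonal operator rows for the interior + axis unknowns
# (nodes 1 .. nr-1; the wall node nr is eliminated by u = 0).
# mu_half: viscosity at the nr-1 midpoints. Returns list(lower, diag, upper)
# for the operator  rho/dt * u - (1/r)d/dr(r mu du/dr)  (rho_dt may be 0 for
# the steady problem).
assemble_operator <- function(grid, mu_half, rho_dt) {
  nr <- grid$nr; h <- grid$h; r <- grid$r
  n <- nr - 1
  rhalf <- (r[-nr] + r[-1]) / 2            # r_{i+1/2}, i = 1..nr-1
  lower <- numeric(n); diagv <- numeric(n); upper <- numeric(n)
  # axis node (finite volume over [0, h/2]): 4 mu_{3/2} (u2 - u1) / h^2
  diagv[1] <- rho_dt + 4 * mu_half[1] / h^2
  upper[1] <- -4 * mu_half[1] / h^2
  if (n >= 2) {
    i <- 2:n
    fp <- rhalf[i] * mu_half[i]          # flux coefficient at i+1/2
    fm <- rhalf[i - 1] * mu_half[i - 1]  # flux coefficient at i-1/2
    lower[i] <- -fm / (r[i] * h^2)
    upper[i] <- -fp / (r[i] * h^2)       # for i = n multiplies wall u = 0
    diagv[i] <- rho_dt + (fp + fm) / (r[i] * h^2)
  }
  upper[n] <- 0
  list(lower = lower, diag = diagv, upper = upper)
}

# One implicit step (or steady solve when rho_dt = 0) with Picard iteration.
# Returns list(u = interior solution, dpdx, iters).
tube_step <- function(grid, rheology, u_old, rho_dt, target = NULL,
                      dpdx = NULL, w = NULL, tol = 1e-8, max_iter = 50L,
                      newtonian = FALSE) {
  n <- grid$nr - 1
  h <- grid$h
  u_it <- u_old
  ones <- rep(1, n)
  rhs0 <- rho_dt * u_old
  for (iter in seq_len(max_iter)) {
    du <- (c(u_it[-1], 0) - u_it) / h          # du/dr at midpoints
    mu_half <- effective_viscosity(abs(du), rheology)
    op <- assemble_operator(grid, mu_half, rho_dt)
    X <- thomas_solve(op$lower, op$diag, op$upper, cbind(rhs0, ones))
    if (is.null(dpdx)) {
      G <- (sum(w * X[, 1]) - target) / sum(w * X[, 2])
    } else {
      G <- dpdx
    }
    u_new <- X[, 1] - G * X[, 2]
    delta <- max(abs(u_new - u_it)) / max(max(abs(u_new)), 1e-300)
    u_it <- u_new
    if (newtonian || delta <= tol) {
      return(list(u = u_it, dpdx = G, iters = iter, delta = delta))
    }
  }
  abort_convergence(
    sprintf("Picard iteration failed to converge within %d iterations (last relative change %.3g).",
            max_iter, delta),
    iters = max_iter, delta = delta)
}

# wall shear stress from a full nodal velocity vector (wall value included)
wss_from_u <- function(u_full, h, rheology) {
  nr <- length(u_full)
  dudr <- (3 * u_full[nr] - 4 * u_full[nr - 1] + u_full[nr - 2]) / (2 * h)
  g <- abs(dudr)
  effective_viscosity(g, rheology) * g
}

#' Solve pulsatile non-Newtonian tube flow
#'
#' Integrates the reduced axisymmetric momentum equation over `n_cycles`
#' cardiac cycles. In the default `"mean_velocity"` mode the cross-section
#' mean velocity is prescribed by the inlet waveform at every step and the
#' uniform axial pressure gradient is solved for (bordered system); in
#' `"dpdx"` mode a pressure-gradient function of time drives the flow, which
#' is the configuration the analytic Womersley solution verifies.
#'
#' Time integration is backward Euler with Picard (lagged-viscosity)
#' iteration; for a constant-viscosity parameter set (`mu0 == mu_inf`) the
#' operator is linear and a single solve per step suffices. The run starts
#' from a quasi-steady profile at the initial waveform value unless `init`
#' is given.
#'
#' @param radius Tube radius (m).
#' @param rheology A [rheology_params()] object or condition name.
#' @param waveform A [waveform_params()] object (drives `"mean_velocity"`
#'   mode and sets the cycle length in both modes).
#' @param nr Number of radial nodes (>= 16; default 101).
#' @param dt Time step (s); default `period / 1000`.
#' @param n_cycles Number of cycles to integrate (default 8); the last
#'   cycle is reported.
#' @param mode `"mean_velocity"` (default) or `"dpdx"`.
#' @param dpdx_fun For `"dpdx"` mode: function of time returning the axial
#'   pressure gradient (Pa/m).
#' @param init Optional initial interior velocity vector (length `nr - 1`,
#'   axis to last interior node) or a full nodal vector of length `nr`.
#' @param picard_tol Relative tolerance of the Picard iteration.
#' @param max_iter Maximum Picard iterations per step.
#' @return An object of class `tube_fit`: a list with the grid, a `summary`
#'   tibble over all steps (`t`, `ubar`, `dpdx`, `wss`, `iters`), a
#'   `profiles` tibble (`t`, `r`, `u`) covering the reported last cycle,
#'   the cycle-to-cycle `periodicity` residual (relative L-infinity), and
#'   the inputs. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' \donttest{
#' fit <- solve_pulsatile_tube(0.0125, "healthy1", nr = 51,
#'                             dt = 0.002, n_cycles = 4)
#' glance(fit)
#' }
#' @export
solve_pulsatile_tube <- function(radius, rheology,
                                 waveform = waveform_params(),
                                 nr = 101, dt = waveform$period / 1000,
                                 n_cycles = 8,
                                 mode = c("mean_velocity", "dpdx"),
                                 dpdx_fun = NULL, init = NULL,
                                 picard_tol = 1e-8, max_iter = 50L) {
  mode <- match.arg(mode)
  rheology <- blood_condition(rheology)
  check_positive(dt, "dt")
  if (!is.numeric(n_cycles) || length(n_cycles) != 1 || n_cycles < 1) {
    abort_invalid("`n_cycles` must be >= 1.")
  }
  if (mode == "dpdx" && !is.function(dpdx_fun)) {
    abort_invalid("`dpdx_fun` must be a function of time in \"dpdx\" mode.")
  }
  grid <- radial_grid(radius, nr)
  n <- grid$nr - 1
  w <- mean_weights(grid)[seq_len(n)]
  rho <- rheology$density
  steps_per_cycle <- max(2L, as.integer(round(waveform$period / dt)))
  dt <- waveform$period / steps_per_cycle
  n_steps <- steps_per_cycle * as.integer(n_cycles)
  newtonian <- rheology$mu0 == rheology$mu_inf

  # initial condition: quasi-steady profile at the t = 0 waveform value
  if (is.null(init)) {
    if (mode == "mean_velocity") {
      v0 <- inlet_velocity(0, waveform)
      st <- tube_step(grid, rheology, rep(0, n), 0, target = v0, w = w,
                      tol = picard_tol, max_iter = 200L,
                      newtonian = newtonian)
      u <- st$u
    } else {
      u <- rep(0, n)
    }
  } else {
    check_finite(init, "init")
    if (length(init) == grid$nr) init <- init[seq_len(n)]
    if (length(init) != n) abort_invalid("`init` has the wrong length.")
    u <- as.double(init)
  }

  times <- seq_len(n_steps) * dt
  ubar <- dpdx_out <- wss_out <- numeric(n_steps)
  iters <- integer(n_steps)
  # keep full profiles for the last two cycles (periodicity check + report)
  keep_from <- if (n_cycles >= 2) n_steps - 2L * steps_per_cycle else 0L
  prof <- matrix(NA_real_, grid$nr, n_steps - keep_from)

  for (s in seq_len(n_steps)) {
    tn <- times[s]
    if (mode == "mean_velocity") {
      st <- tube_step(grid, rheology, u, rho / dt,
                      target = inlet_velocity(tn, waveform), w = w,
                      tol = picard_tol, max_iter = max_iter,
                      newtonian = newtonian)
    } else {
      st <- tube_step(grid, rheology, u, rho / dt, dpdx = dpdx_fun(tn),
                      tol = picard_tol, max_iter = max_iter,
                      newtonian = newtonian)
    }
    u <- st$u
    u_full <- c(u, 0)
    ubar[s] <- sum(w * u)
    dpdx_out[s] <- st$dpdx
    wss_out[s] <- wss_from_u(u_full, grid$h, rheology)
    iters[s] <- st$iters
    if (s > keep_from) prof[, s - keep_from] <- u_full
  }

  # cycle-to-cycle periodicity on the stored profiles
  periodicity <- NA_real_
  if (n_cycles >= 2) {
    last <- prof[, steps_per_cycle + seq_len(steps_per_cycle), drop = FALSE]
    prev <- prof[, seq_len(steps_per_cycle), drop = FALSE]
    periodicity <- max(abs(last - prev)) / max(abs(last))
    report <- last
    report_t <- times[(n_steps - steps_per_cycle + 1):n_steps]
  } else {
    report <- prof
    report_t <- times[(keep_from + 1):n_steps]
  }

  profiles <- tibble::tibble(
    t = rep(report_t, each = grid$nr),
    r = rep(grid$r, times = length(report_t)),
    u = as.double(report)
  )

  structure(list(
    radius = radius, grid = grid, rheology = rheology, waveform = waveform,
    mode = mode, dt = dt, n_cycles = n_cycles,
    steps_per_cycle = steps_per_cycle,
    summary = tibble::tibble(t = times, ubar = ubar, dpdx = dpdx_out,
                             wss = wss_out, iters = iters),
    profiles = profiles, periodicity = periodicity
  ), class = "tube_fit")
}

#' @export
print.tube_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<tube_fit: %s, R = %.4g m, nr = %d, dt = %.4g s, %g cycles (%s mode)>\n",
    x$rheology$name, x$radius, x$grid$nr, x$dt, x$n_cycles, x$mode))
  cat(sprintf(
    "  last cycle: mean WSS %.4g Pa, peak WSS %.4g Pa, peak |dpdx| %.4g Pa/m\n",
    g$wss_mean, g$wss_max, g$dpdx_peak))
  cat(sprintf("  periodicity residual %.3g, mean Picard iterations %.2f\n",
              x$periodicity, g$picard_iters))
  invisible(x)
}

#' Steady fully developed tube flow
#'
#' Solves the steady analogue of [solve_pulsatile_tube()] at a prescribed
#' cross-section mean velocity. For a constant viscosity this reproduces
#' the Poiseuille profile (discretely exact for the parabolic solution).
#'
#' @inheritParams solve_pulsatile_tube
#' @param ubar Cross-section mean velocity (m/s).
#' @return A [radial_profile()] with the solved-for pressure gradient in
#'   its `dpdx` attribute.
#' @examples
#' p <- solve_steady_tube(0.01, rheology_params("newt", 0.5, 1, 0.0035, 0.0035),
#'                        ubar = 0.2, nr = 51)
#' attr(p, "dpdx")
#' @export
solve_steady_tube <- function(radius, rheology, ubar, nr = 101,
                              picard_tol = 1e-10, max_iter = 200L) {
  rheology <- blood_condition(rheology)
  check_scalar(ubar, "ubar")
  grid <- radial_grid(radius, nr)
  n <- grid$nr - 1
  w <- mean_weights(grid)[seq_len(n)]
  newtonian <- rheology$mu0 == rheology$mu_inf
  # Poiseuille-shaped initial iterate
  u0 <- 2 * ubar * (1 - (grid$r[seq_len(n)] / radius)^2)
  st <- tube_step(grid, rheology, u0, 0, target = ubar, w = w,
                  tol = picard_tol, max_iter = max_iter,
                  newtonian = newtonian)
  radial_profile(grid$r, c(st$u, 0), t = NA_real_, dpdx = st$dpdx)
}

#' Wall shear stress of a radial profile
#'
#' Magnitude of the viscous traction at the wall,
#' \eqn{\tau_w = \mu_{eff}(\dot\gamma_w)\,|du/dr|_{wall}}, with the wall
#' gradient from a one-sided second-order difference. For a Poiseuille
#' profile with constant viscosity this equals \eqn{4\mu\bar u/R}.
#'
#' @param profile A [radial_profile()] (needs at least three nodes).
#' @param rheology A [rheology_params()] object or condition name.
#' @return Wall shear stress (Pa), non-negative.
#' @export
wall_shear_stress <- function(profile, rheology) {
  rheology <- blood_condition(rheology)
  if (!is.data.frame(profile) || !all(c("r", "u") %in% names(profile))) {
    abort_invalid("`profile` must have columns `r` and `u`.")
  }
  nr <- nrow(profile)
  if (nr < 3) abort_invalid("`profile` needs at least 3 nodes.")
  h <- diff(profile$r)
  if (any(h <= 0) || any(abs(h - h[1]) > 1e-9 * h[1])) {
    abort_invalid("`profile` must be on a uniform, increasing radial grid.")
  }
  wss_from_u(profile$u, h[1], rheology)
}

#' Skin friction coefficient
#'
#' Nondimensionalizes a wall shear stress by the dynamic pressure:
#' \eqn{C_f = \tau_w / (0.5 \rho v^2)}.
#'
#' @param tau_w Wall shear stress (Pa), non-negative.
#' @param density Fluid density (kg/m^3), positive.
#' @param v_ref Reference velocity (m/s), positive.
#' @return Dimensionless skin friction coefficient.
#' @examples
#' skin_friction(0.28, 1060, 0.2)
#' @export
skin_friction <- function(tau_w, density, v_ref) {
  check_non_negative(tau_w, "tau_w")
  check_positive(density, "density")
  check_positive(v_ref, "v_ref")
  tau_w / (0.5 * density * v_ref^2)
}

#' Reynolds number
#'
#' `Re = density * velocity * diameter / viscosity`, conventionally based
#' on the peak systolic velocity and the vessel diameter.
#'
#' @param density Fluid density (kg/m^3).
#' @param v_peak Reference (peak systolic) velocity (m/s).
#' @param diameter Vessel diameter (m).
#' @param mu_ref Reference dynamic viscosity (Pa s).
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds_number(1060, 0.5, 0.025, 0.0035)
#' @export
reynolds_number <- function(density, v_peak, diameter, mu_ref) {
  check_positive(density, "density"); check_positive(v_peak, "v_peak")
  check_positive(diameter, "diameter"); check_positive(mu_ref, "mu_ref")
  density * v_peak * diameter / mu_ref
}
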