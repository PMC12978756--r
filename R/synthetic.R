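# Closed-form reference flows and idealized inputs. Everything here is
# deterministic and generated in code; these are the oracles the solver and
# the helicity diagnostic are verified against.

# Bessel J0 for complex argument, by power series
#   J0(z) = sum_k (-z^2/4)^k / (k!)^2.
# Adequate to near machine precision for |z| up to ~40, which covers the
# Womersley numbers arising at aortic scale (alpha ~ 25). Base R's besselJ
# is real-only, hence this small complex implementation.
besselJ0_complex <- function(z) {
  z <- as.complex(z)
  term <- rep(1 + 0i, length(z))
  total <- term
  zz <- -(z * z) / 4
  for (k in 1:300) {
    term <- term * zz / (k * k)
    total <- total + term
    if (all(Mod(term) <= 1e-17 * (Mod(total) + 1e-300))) break
  }
  total
}

#' Womersley reference flow
#'
#' The classical analytic solution for laminar oscillatory flow in a rigid
#' circular pipe driven by a sinusoidal axial pressure gradient
#' `dpdx(t) = -A cos(omega t)`:
#' \deqn{u(r, t) = \Re\left\{\frac{A}{i\rho\omega}
#'   \left[1 - \frac{J_0(\beta r)}{J_0(\beta R)}\right] e^{i\omega t}\right\},
#'   \qquad \beta = \sqrt{-i\omega\rho/\mu}.}
#' The Womersley number is \eqn{\alpha = R\sqrt{\omega\rho/\mu}}. As
#' \eqn{\alpha \to 0} the profile approaches quasi-steady Poiseuille flow
#' with the instantaneous pressure gradient.
#'
#' @param radius Pipe radius (m).
#' @param density Fluid density (kg/m^3).
#' @param viscosity Constant dynamic viscosity (Pa s).
#' @param dpdx_amplitude Pressure-gradient amplitude `A` (Pa/m).
#' @param omega Angular frequency (rad/s).
#' @return A list with the inputs plus the derived Womersley number
#'   `alpha`, of class `womersley_reference`.
#' @export
womersley_reference <- function(radius, density, viscosity,
                                dpdx_amplitude, omega) {
  check_positive(radius, "radius"); check_positive(density, "density")
  check_positive(viscosity, "viscosity"); check_positive(omega, "omega")
  check_scalar(dpdx_amplitude, "dpdx_amplitude")
  structure(list(radius = radius, density = density, viscosity = viscosity,
                 dpdx_amplitude = dpdx_amplitude, omega = omega,
                 alpha = radius * sqrt(omega * density / viscosity)),
            class = "womersley_reference")
}

#' @rdname womersley_reference
#' @param ref A `womersley_reference`.
#' @param r Radii (m) in `[0, radius]`.
#' @param t Time (s), scalar.
#' @return `womersley_profile`: axial velocity (m/s) at the requested
#'   radii; exactly zero at the wall. `womersley_dpdx`: the driving
#'   pressure gradient at time `t`.
#' @export
womersley_profile <- function(ref, r, t) {
  check_finite(r, "r"); check_scalar(t, "t")
  if (any(r < 0 | r > ref$radius)) {
    abort_invalid("`r` must lie within [0, radius].")
  }
  beta <- sqrt(complex(real = 0,
                       imaginary = -ref$omega * ref$density / ref$viscosity))
  uhat <- (ref$dpdx_amplitude / (1i * ref$density * ref$omega)) *
    (1 - besselJ0_complex(beta * r) / besselJ0_complex(beta * ref$radius))
  Re(uhat * exp(1i * ref$omega * t))
}

#' @rdname womersley_reference
#' @export
womersley_dpdx <- function(ref, t) {
  check_finite(t, "t")
  -ref$dpdx_amplitude * cos(ref$omega * t)
}

#' Poiseuille reference profile
#'
#' Steady fully developed parabolic pipe flow
#' \eqn{u(r) = (-dpdx / 4\mu)(R^2 - r^2)}: centreline velocity is twice
#' the cross-section mean, the mean is \eqn{(-dpdx) R^2 / 8\mu}, and the
#' wall shear stress is \eqn{|dpdx| R / 2}.
#'
#' @param radius Pipe radius (m).
#' @param viscosity Dynamic viscosity (Pa s), positive.
#' @param dpdx Axial pressure gradient (Pa/m); negative drives flow in +x.
#' @param r Radii (m) in `[0, radius]`.
#' @return Axial velocity (m/s) at `r`.
#' @examples
#' poiseuille_profile(0.01, 0.0035, -11.2, c(0, 0.005, 0.01))
#' @export
poiseuille_profile <- function(radius, viscosity, dpdx, r) {
  check_positive(radius, "radius"); check_positive(viscosity, "viscosity")
  check_scalar(dpdx, "dpdx"); check_finite(r, "r")
  if (any(r < 0 | r > radius)) abort_invalid("`r` must lie within [0, radius].")
  (-dpdx / (4 * viscosity)) * (radius^2 - r^2)
}

#' Arnold-Beltrami-Childress (ABC) flow on a periodic grid
#'
#' The Beltrami field
#' `u = A sin z + C cos y`, `v = B sin x + A cos z`,
#' `w = C sin y + B cos x` sampled on a periodic grid over `[0, 2*pi)^3`.
#' Its curl equals the field itself, so the exact helicity density equals
#' the squared speed everywhere — the standard oracle for the helicity
#' diagnostic. The field is divergence-free.
#'
#' @param n Grid points per axis (>= 8).
#' @param A,B,C Component amplitudes (m/s).
#' @return A periodic [gridded_field()] with spacing `2*pi/n`.
#' @examples
#' f <- abc_field(16)
#' @export
abc_field <- function(n, A = 1, B = 1, C = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 8 || n != round(n)) {
    abort_invalid("`n` must be an integer >= 8.")
  }
  check_scalar(A, "A"); check_scalar(B, "B"); check_scalar(C, "C")
  x <- 2 * pi * (seq_len(n) - 1) / n
  X <- array(x, c(n, n, n))
  Y <- array(rep(x, each = n), c(n, n, n))
  Z <- array(rep(x, each = n * n), c(n, n, n))
  gridded_field(u = A * sin(Z) + C * cos(Y),
                v = B * sin(X) + A * cos(Z),
                w = C * sin(Y) + B * cos(X),
                spacing = 2 * pi / n, periodic = TRUE)
}

#' Solid-body rotation field
#'
#' `u = (-omega0 * y, omega0 * x, 0)` on a centred grid: constant vorticity
#' `(0, 0, 2 omega0)` perpendicular to the velocity, hence zero helicity.
#' Useful as a null oracle for [helicity_field()].
#'
#' @param n Grid points per axis (>= 3).
#' @param omega0 Rotation rate (rad/s).
#' @param extent Half-width of the cube (m).
#' @return A [gridded_field()].
#' @export
rotation_field <- function(n = 16, omega0 = 1, extent = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 3) {
    abort_invalid("`n` must be an integer >= 3.")
  }
  x <- seq(-extent, extent, length.out = n)
  X <- array(x, c(n, n, n))
  Y <- array(rep(x, each = n), c(n, n, n))
  gridded_field(u = -omega0 * Y, v = omega0 * X,
                w = array(0, c(n, n, n)), spacing = x[2] - x[1])
}
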