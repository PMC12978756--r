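#' Carreau shear-thinning rheological parameter set
#'
#' Bundles the constants of the Carreau effective-viscosity law
#' \deqn{\mu_{eff}(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#'       \left(1 + (\lambda\dot\gamma)^2\right)^{(k-1)/2}}
#' together with hematocrit (metadata only; it does not enter the law) and
#' blood density. The built-in blood conditions are available through
#' [blood_condition()] and [blood_conditions()].
#'
#' @param name Label for the parameter set.
#' @param k Power-law index (dimensionless), must satisfy `0 < k < 1` for
#'   shear-thinning behaviour.
#' @param lambda Time constant (s), positive.
#' @param mu0 Zero-shear viscosity (Pa s).
#' @param mu_inf Infinite-shear viscosity (Pa s); requires
#'   `mu0 >= mu_inf > 0`.
#' @param hematocrit Red-cell volume fraction in `[0, 1]`; stored as
#'   metadata.
#' @param density Blood density (kg/m^3), default 1060.
#' @return An object of class `rheology_params`.
#' @examples
#' hb <- rheology_params("custom", k = 0.4, lambda = 10, mu0 = 0.02,
#'                       mu_inf = 0.003, hematocrit = 0.42)
#' effective_viscosity(c(0, 1, 100), hb)
#' @export
rheology_params <- function(name, k, lambda, mu0, mu_inf,
                            hematocrit = NA_real_, density = 1060) {
  check_scalar(k, "k"); check_scalar(lambda, "lambda")
  check_scalar(mu0, "mu0"); check_scalar(mu_inf, "mu_inf")
  check_scalar(density, "density")
  if (k <= 0 || k >= 1) abort_invalid("`k` must lie strictly between 0 and 1.")
  if (lambda <= 0) abort_invalid("`lambda` must be positive.")
  if (mu_inf <= 0 || mu0 < mu_inf) {
    abort_invalid("viscosity plateaus must satisfy mu0 >= mu_inf > 0.")
  }
  if (density <= 0) abort_invalid("`density` must be positive.")
  if (!is.na(hematocrit) && (hematocrit < 0 || hematocrit > 1)) {
    abort_invalid("`hematocrit` must lie in [0, 1].")
  }
  structure(
    list(name = as.character(name), k = k, lambda = lambda, mu0 = mu0,
         mu_inf = mu_inf, hematocrit = hematocrit, density = density),
    class = "rheology_params"
  )
}

#' @export
print.rheology_params <- function(x, ...) {
  cat(sprintf(
    "<rheology_params: %s>\n  k = %.4g, lambda = %.4g s\n  mu0 = %.4g Pa s, mu_inf = %.4g Pa s\n  hematocrit = %s, density = %g kg/m^3\n",
    x$name, x$k, x$lambda, x$mu0, x$mu_inf,
    if (is.na(x$hematocrit)) "NA" else sprintf("%.2f", x$hematocrit),
    x$density))
  invisible(x)
}

# Frozen registry: Carreau constants for the four blood conditions.
# Hematocrit is descriptive metadata; density is 1060 kg/m^3 throughout.
.blood_registry <- list(
  anemic   = list(k = 0.33,   lambda = 12.448, mu0 = 0.0178, mu_inf = 0.00257,
                  hematocrit = 0.25),
  diabetic = list(k = 0.39,   lambda = 103.09, mu0 = 0.8592, mu_inf = 0.00802,
                  hematocrit = 0.65),
  healthy1 = list(k = 0.48,   lambda = 39.418, mu0 = 0.0161, mu_inf = 0.00345,
                  hematocrit = 0.45),
  healthy2 = list(k = 0.3568, lambda = 3.313,  mu0 = 0.056,  mu_inf = 0.0035,
                  hematocrit = 0.45)
)

#' Built-in blood-condition registry
#'
#' Returns the Carreau parameter sets for the four modelled blood
#' conditions: anemic, diabetic, and two healthy profiles. All share a
#' density of 1060 kg/m^3. The parameters are validated against the
#' `rheology_params` invariants on every access.
#'
#' @return A tibble with one row per condition and columns `condition`,
#'   `k`, `lambda`, `mu0`, `mu_inf`, `hematocrit`, `density`.
#' @seealso [blood_condition()] for a single parameter set.
#' @examples
#' blood_conditions()
#' @export
blood_conditions <- function() {
  purrr::map_dfr(names(.blood_registry), function(nm) {
    p <- blood_condition(nm)
    tibble::tibble(condition = nm, k = p$k, lambda = p$lambda, mu0 = p$mu0,
                   mu_inf = p$mu_inf, hematocrit = p$hematocrit,
                   density = p$density)
  })
}

#' @rdname blood_conditions
#' @param condition One of `"anemic"`, `"diabetic"`, `"healthy1"`,
#'   `"healthy2"`, or a `rheology_params` object (returned unchanged, which
#'   lets pipeline functions accept custom conditions).
#' @export
blood_condition <- function(condition) {
  if (inherits(condition, "rheology_params")) return(condition)
  if (!is.character(condition) || length(condition) != 1 ||
      !condition %in% names(.blood_registry)) {
    abort_invalid(sprintf(
      "unknown blood condition; expected one of %s or a rheology_params object.",
      paste0('"', names(.blood_registry), '"', collapse = ", ")))
  }
  p <- .blood_registry[[condition]]
  rheology_params(condition, k = p$k, lambda = p$lambda, mu0 = p$mu0,
                  mu_inf = p$mu_inf, hematocrit = p$hematocrit,
                  density = 1060)
}

#' Carreau effective viscosity
#'
#' Evaluates the shear-thinning effective viscosity
#' \eqn{\mu_{eff}(\dot\gamma)} (see [rheology_params()]). The transition
#' factor is computed through `exp`/`log1p` with the product
#' \eqn{\lambda\dot\gamma} clamped above 1e15, which preserves both
#' plateaus exactly and avoids overflow: the value always lies in
#' `[mu_inf, mu0]` and is non-increasing in the shear rate.
#'
#' @param shear_rate Shear rate(s) in 1/s, finite and non-negative.
#' @param params A [rheology_params()] object or condition name.
#' @return Effective viscosity in Pa s, same length as `shear_rate`.
#' @examples
#' effective_viscosity(0, blood_condition("diabetic"))     # zero-shear plateau
#' effective_viscosity(1e10, blood_condition("anemic"))    # high-shear plateau
#' @export
effective_viscosity <- function(shear_rate, params) {
  params <- blood_condition(params)
  check_non_negative(shear_rate, "shear_rate")
  lg <- pmin(params$lambda * shear_rate, 1e15)
  params$mu_inf + (params$mu0 - params$mu_inf) *
    exp(((params$k - 1) / 2) * log1p(lg * lg))
}

#' Shear-rate magnitude from a velocity-gradient tensor
#'
#' Computes \eqn{\dot\gamma = \sqrt{2\,D : D}} where `D` is the symmetric
#' part of the 3x3 velocity-gradient tensor — the standard second invariant
#' of the rate-of-strain tensor. For simple shear with `du/dy = s` this
#' returns `s`; a pure rotation returns 0.
#'
#' @param grad_u 3x3 numeric matrix with entry `[i, j] = d u_i / d x_j`
#'   (units 1/s).
#' @return Scalar shear rate in 1/s, non-negative.
#' @examples
#' g <- matrix(0, 3, 3); g[1, 2] <- 50
#' shear_rate_magnitude(g)  # 50
#' @export
shear_rate_magnitude <- function(grad_u) {
  if (!is.matrix(grad_u) || !all(dim(grad_u) == c(3, 3))) {
    abort_invalid("`grad_u` must be a 3x3 matrix.")
  }
  check_finite(as.numeric(grad_u), "grad_u")
  D <- (grad_u + t(grad_u)) / 2
  sqrt(2 * sum(D * D))
}

#' Viscosity-versus-shear-rate curve
#'
#' Tabulates [effective_viscosity()] on a shear-rate grid, for plotting the
#' characteristic shear-thinning curves of the blood conditions or for CSV
#' export via [export_viscosity_curve()].
#'
#' @inheritParams effective_viscosity
#' @param shear_rates Non-negative shear rates (1/s); defaults to a
#'   logarithmic grid spanning 1e-2 to 1e4.
#' @return A tibble with columns `condition`, `shear_rate`, `mu_eff`,
#'   non-increasing in `shear_rate`.
#' @examples
#' viscosity_curve(blood_condition("healthy1"))
#' @export
viscosity_curve <- function(params, shear_rates = 10^seq(-2, 4, length.out = 121)) {
  params <- blood_condition(params)
  if (length(shear_rates) == 0) {
    return(tibble::tibble(condition = character(), shear_rate = double(),
                          mu_eff = double()))
  }
  check_non_negative(shear_rates, "shear_rates")
  tibble::tibble(condition = params$name, shear_rate = as.double(shear_rates),
                 mu_eff = effective_viscosity(shear_rates, params))
}
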