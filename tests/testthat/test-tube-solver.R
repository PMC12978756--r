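test_that("steady constant-viscosity solve recovers Poiseuille to 0.1%", {
  mu <- 0.0035; R <- 0.01; ubar <- 0.2
  newt <- newtonian_params(mu)
  prof <- solve_steady_tube(R, newt, ubar = ubar, nr = 101)
  expect_equal(prof$u[1], 2 * ubar, tolerance = 1e-3)             # centreline
  expect_equal(attr(prof, "dpdx"), -8 * mu * ubar / R^2, tolerance = 1e-3)
  expect_equal(wall_shear_stress(prof, newt), 4 * mu * ubar / R,
               tolerance = 1e-3)
  # full radial shape against the analytic parabola
  ua <- poiseuille_profile(R, mu, attr(prof, "dpdx"), prof$r)
  expect_lt(max(abs(prof$u - ua)) / (2 * ubar), 1e-3)
})

test_that("pulsatile solve with a constant waveform reaches the steady limit", {
  mu <- 0.0035; R <- 0.01; ubar <- 0.2
  newt <- newtonian_params(mu)
  wf <- waveform_params(amplitude = 0, diastolic_level = ubar)
  fit <- solve_pulsatile_tube(R, newt, wf, nr = 101, dt = 0.002, n_cycles = 2)
  s <- tidy(fit)
  expect_equal(s$wss[nrow(s)], 4 * mu * ubar / R, tolerance = 1e-3)
  expect_equal(s$dpdx[nrow(s)], -8 * mu * ubar / R^2, tolerance = 1e-3)
})

test_that("the prescribed-flow constraint holds at every step", {
  fit <- solve_pulsatile_tube(0.0125, "healthy2", nr = 41, dt = 0.005,
                              n_cycles = 2)
  target <- inlet_velocity(fit$summary$t, fit$waveform)
  expect_lt(max(abs(fit$summary$ubar - target)) / max(abs(target)), 1e-8)
})

test_that("shear-thinning path matches the constant-viscosity path in the Newtonian limit", {
  mu <- 0.004
  exact_newt <- newtonian_params(mu)                       # single-solve path
  near_newt <- rheology_params("near", k = 0.5, lambda = 1,
                               mu0 = mu, mu_inf = mu * (1 - 1e-15))
  wf <- waveform_params()
  f1 <- solve_pulsatile_tube(0.01, exact_newt, wf, nr = 41, dt = 0.005,
                             n_cycles = 2)
  f2 <- solve_pulsatile_tube(0.01, near_newt, wf, nr = 41, dt = 0.005,
                             n_cycles = 2)   # full Picard path
  expect_lt(max(abs(f1$profiles$u - f2$profiles$u)) / max(abs(f1$profiles$u)),
            1e-10)
})

test_that("solver matches the analytic Womersley solution and converges in dt", {
  ref <- womersley_reference(0.0125, 1060, 0.0035, 100, 4 * pi)
  e_coarse <- womersley_solver_error(ref, nr = 101, dt = 0.5 / 500)
  e_fine <- womersley_solver_error(ref, nr = 101, dt = 0.5 / 2000)
  expect_lt(e_coarse$l2, 0.02)
  expect_lt(e_fine$l2, 0.005)
  # backward Euler: roughly first-order reduction with dt
  expect_gt(e_coarse$l2 / e_fine$l2, 2.5)
})

test_that("Womersley WSS error decreases monotonically under grid refinement", {
  ref <- womersley_reference(0.0125, 1060, 0.0035, 100, 4 * pi)
  errs <- sapply(c(51, 101, 201), function(nr) {
    womersley_solver_error(ref, nr = nr, dt = 0.5 / 1000)$wss_abs
  })
  expect_true(all(diff(errs) < 0))
})

test_that("non-Newtonian profiles are blunter than Newtonian at the zero-shear viscosity", {
  an <- blood_condition("anemic")
  ubar <- 0.2
  p_carreau <- solve_steady_tube(0.0125, an, ubar = ubar, nr = 101)
  p_newt <- solve_steady_tube(0.0125, newtonian_params(an$mu0), ubar = ubar,
                              nr = 101)
  expect_lt(p_carreau$u[1], p_newt$u[1])
  # same mean by construction, so bluntness shows at the centreline
  expect_equal(p_newt$u[1], 2 * ubar, tolerance = 1e-3)
})

test_that("cycle-averaged WSS and peak |dpdx| rank the conditions like their viscosity", {
  gl <- lapply(c("anemic", "diabetic", "healthy1", "healthy2"), function(cond) {
    glance(solve_pulsatile_tube(0.0125, cond, nr = 41, dt = 0.5 / 200,
                                n_cycles = 6))
  })
  gl <- do.call(rbind, gl)
  wss <- setNames(gl$wss_mean, gl$condition)
  dpdx <- setNames(gl$dpdx_peak, gl$condition)
  expect_gt(wss[["diabetic"]], wss[["healthy1"]])
  expect_gt(wss[["diabetic"]], wss[["healthy2"]])
  expect_gt(wss[["healthy1"]], wss[["anemic"]])
  expect_gt(wss[["healthy2"]], wss[["anemic"]])
  expect_gt(dpdx[["diabetic"]], dpdx[["healthy1"]])
  expect_gt(dpdx[["diabetic"]], dpdx[["healthy2"]])
  expect_gt(dpdx[["healthy1"]], dpdx[["anemic"]])
  expect_gt(dpdx[["healthy2"]], dpdx[["anemic"]])
})

test_that("wall shear stress helper matches closed forms and rejects bad input", {
  r <- seq(0, 0.01, length.out = 101)
  newt <- newtonian_params(0.0035)
  pois <- radial_profile(r, poiseuille_profile(0.01, 0.0035, -56, r))
  expect_equal(wall_shear_stress(pois, newt), 0.28, tolerance = 1e-10)
  # uniform (zero-gradient) profile carries no wall shear
  expect_equal(wall_shear_stress(radial_profile(r, rep(0, 101)), newt), 0)
  expect_error(wall_shear_stress(radial_profile(c(0, 1e-4), c(0.1, 0)), newt),
               class = "pulsarch_invalid_input")
  bad <- tibble::tibble(r = c(0, 0.1, 0.1, 0.3), u = c(1, 1, 1, 0))
  expect_error(wall_shear_stress(bad, newt), class = "pulsarch_invalid_input")
})

test_that("skin friction and Reynolds number follow their definitions", {
  expect_equal(skin_friction(0.28, 1060, 0.2), 0.28 / (0.5 * 1060 * 0.04))
  expect_identical(skin_friction(0, 1060, 0.3), 0)
  expect_equal(skin_friction(0.28, 1060, 0.4), skin_friction(0.28, 1060, 0.2) / 4)
  expect_equal(reynolds_number(1060, 0.5, 0.025, 0.0035), 3785.714286,
               tolerance = 1e-6)
  expect_equal(reynolds_number(1060, 0.5, 0.025, 0.007),
               reynolds_number(1060, 0.5, 0.025, 0.0035) / 2)
  expect_error(skin_friction(0.28, 1060, 0), class = "pulsarch_invalid_input")
  expect_error(reynolds_number(1060, 0.5, -0.025, 0.0035),
               class = "pulsarch_invalid_input")
})

test_that("non-convergent Picard iteration raises a convergence error", {
  expect_error(
    solve_pulsatile_tube(0.0125, "diabetic", nr = 41, dt = 0.005,
                         n_cycles = 1, max_iter = 1L),
    class = "pulsarch_convergence_error")
})
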