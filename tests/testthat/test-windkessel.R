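test_that("parameter estimation follows the 5/95 split and decay constant", {
  wk <- estimate_windkessel(13332, 1e-4, tau = 1.0)
  expect_equal(wk$R1, 6.666e6, tolerance = 1e-12)
  expect_equal(wk$R2, 1.26654e8, tolerance = 1e-12)
  expect_equal(wk$C, 7.8955263947364e-9, tolerance = 1e-9)
  set.seed(11)
  for (i in 1:20) {
    p <- 10^stats::runif(1, 3, 5); q <- 10^stats::runif(1, -6, -3)
    tau <- stats::runif(1, 0.2, 3)
    wk <- estimate_windkessel(p, q, tau)
    expect_lt(abs(wk$R1 / (wk$R1 + wk$R2) - 0.05), 1e-12)
    expect_lt(abs(wk$C * wk$R2 - tau) / tau, 1e-12)
  }
  expect_error(estimate_windkessel(-1, 1e-4), class = "pulsarch_invalid_input")
  expect_error(estimate_windkessel(1e4, 0), class = "pulsarch_invalid_input")
})

test_that("P-form and Pc-form of the implicit update are equivalent", {
  wk <- estimate_windkessel(13332, 1e-4)
  s1 <- windkessel_state(Pc = 12000, Q = 1e-4, t = 0, params = wk)
  s2 <- s1
  set.seed(3)
  for (i in 1:200) {
    Qn <- 1e-4 * (1 + 0.5 * sin(i / 7)) + stats::rnorm(1, 0, 1e-6)
    s1 <- windkessel_step(s1, Qn, wk, dt = 0.01, form = "Pc")
    s2 <- windkessel_step(s2, Qn, wk, dt = 0.01, form = "P")
    # consistency P = Pc + R1 Q at every accepted step
    expect_lt(abs(s1$P - s1$Pc - wk$R1 * s1$Q) / abs(s1$P), 1e-12)
    expect_lt(abs(s1$P - s2$P) / abs(s1$P), 1e-12)
  }
})

test_that("constant flow drives the pressure to the analytic steady state", {
  wk <- estimate_windkessel(13332, 1e-4)
  Q <- 8e-5
  st <- windkessel_state(Pc = 0, Q = Q, t = 0, params = wk)
  for (i in 1:2000) st <- windkessel_step(st, Q, wk, dt = 0.01)
  expect_equal(st$P, (wk$R1 + wk$R2) * Q, tolerance = 1e-3)
})

test_that("zero-flow decay matches exp(-t / R2C) at the documented accuracy", {
  wk <- windkessel_params(R1 = 1e6, R2 = 1e8, C = 1e-8)  # R2 C = 1 s
  st <- windkessel_state(Pc = 1e4, Q = 0, t = 0, params = wk)
  for (i in 1:100) st <- windkessel_step(st, 0, wk, dt = 0.01)
  expect_equal(st$Pc, 1e4 * exp(-1), tolerance = 5e-3)
})

test_that("backward Euler converges to the ODE oracle at first order", {
  skip_if_not_installed("deSolve")
  wk <- estimate_windkessel(13332, 1e-4)
  Q_fun <- function(t) 1e-4 * (1 + 0.4 * sin(4 * pi * t) + 0.2 * cos(8 * pi * t))
  Pc0 <- 1e4
  errs <- sapply(c(0.02, 0.01, 0.005, 0.0025), function(dt) {
    t <- seq(0, 1, by = dt)
    sim <- windkessel_simulate(tibble::tibble(t = t, Q = Q_fun(t)), wk, Pc0 = Pc0)
    ref <- rcr_ode_oracle(wk, Q_fun, Pc0, t)
    max(abs(sim$Pc - ref))
  })
  expect_true(all(diff(errs) < 0))
  rates <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(rates > 0.8 & rates < 1.3))   # first-order in dt
})

test_that("the update is a contraction for any dt without overflow", {
  wk <- estimate_windkessel(13332, 1e-4)
  for (dt in 10^seq(-5, 0)) {
    beta <- wk$R2 * wk$C / dt
    expect_lt(beta / (1 + beta), 1)
    st <- windkessel_state(Pc = 1e5, Q = 0, t = 0, params = wk)
    for (i in 1:50) st <- windkessel_step(st, 1e-4 * sin(i), wk, dt = dt)
    expect_true(is.finite(st$P))
  }
})

test_that("periodic flow reaches a cycle-periodic pressure with the RCR mean", {
  wk <- estimate_windkessel(13332, 1e-4, tau = 1)
  dt <- 0.0025
  t <- seq(0, 10 * 0.5, by = dt)     # ten cycles; decay constant is 0.95 s
  area_Q <- 1e-4 / mean_inlet_velocity()
  Q <- inlet_velocity(t) * area_Q          # waveform-shaped, mean 1e-4
  sim <- windkessel_simulate(tibble::tibble(t = t, Q = Q), wk, Pc0 = 13332)
  spc <- 0.5 / dt
  n <- nrow(sim)
  last <- (n - spc + 1):n
  per <- max(abs(sim$P[last] - sim$P[last - spc])) / max(abs(sim$P[last]))
  expect_lt(per, 1e-3)
  # cycle mean approaches Rtot * mean flow = the estimation target pressure
  expect_equal(mean(sim$P[last]), 13332, tolerance = 0.01)
  # diastolic decay time constant ~ R2 C: fit the log-slope over the
  # latter half of the final diastole, offset to the plateau asymptote
  dia <- sim$t > 4.875 & sim$t <= 5
  Pc_rel <- sim$Pc[dia] - wk$R2 * 0.1 * area_Q
  fitc <- stats::coef(stats::lm(log(Pc_rel) ~ sim$t[dia]))
  expect_equal(-1 / fitc[[2]], wk$R2 * wk$C, tolerance = 0.15)
})

test_that("linearity: zero-mean flow gives near-zero mean pressure and C drops out", {
  wk <- windkessel_params(R1 = 5e6, R2 = 9.5e7, C = 1e-8)
  dt <- 0.002
  t <- seq(0, 10 * 0.5, by = dt)
  Q <- 1e-4 * sin(4 * pi * t)
  sim <- windkessel_simulate(tibble::tibble(t = t, Q = Q), wk, Pc0 = 0)
  spc <- 0.5 / dt
  last <- (nrow(sim) - spc + 1):nrow(sim)
  expect_lt(abs(mean(sim$P[last])), 0.01 * max(abs(sim$P[last])))
  # doubling the compliance leaves the cycle-mean pressure unchanged
  Qw <- inlet_velocity(t) * 1e-3
  Pc0 <- wk$R2 * mean(Qw)    # start each run at its cycle-mean asymptote
  m1 <- windkessel_simulate(tibble::tibble(t = t, Q = Qw), wk, Pc0 = Pc0)
  wk2 <- windkessel_params(R1 = wk$R1, R2 = wk$R2, C = 2 * wk$C)
  m2 <- windkessel_simulate(tibble::tibble(t = t, Q = Qw), wk2, Pc0 = Pc0)
  expect_equal(mean(m1$P[last]), mean(m2$P[last]), tolerance = 0.01)
})

test_that("simulate rejects non-uniform or reversed time grids", {
  wk <- estimate_windkessel(13332, 1e-4)
  bad <- tibble::tibble(t = c(0, 0.01, 0.03), Q = c(1, 1, 1) * 1e-4)
  expect_error(windkessel_simulate(bad, wk), class = "pulsarch_invalid_input")
  rev <- tibble::tibble(t = c(0, -0.01, -0.02), Q = rep(1e-4, 3))
  expect_error(windkessel_simulate(rev, wk), class = "pulsarch_invalid_input")
  st <- windkessel_state(Pc = 1e4, Q = 0, t = 0, params = wk)
  expect_error(windkessel_step(st, 1e-4, wk, dt = 0), class = "pulsarch_invalid_input")
})
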