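test_that("closed-form membrane potential behaves like the analytic solution", {
  p <- lif_params(resistance = 1, tau_m = 10, threshold = 1, dt = 0.01)
  expect_identical(membrane_closed_form(p, 2, 0), 0)
  # asymptote R*I0 at long times
  expect_equal(membrane_closed_form(p, 2, 50 * 10), 2, tolerance = 1e-9)
  # half-way point: at t = tau*ln(2) the membrane is half the asymptote
  expect_equal(membrane_closed_form(p, 2, 10 * log(2)), 1, tolerance = 1e-12)
  expect_error(membrane_closed_form(p, 2, -1), ">= 0")
})

test_that("interspike interval and firing rate follow the closed forms", {
  p <- lif_params(resistance = 1, tau_m = 10, threshold = 1, dt = 0.01)
  expect_equal(interspike_interval(p, 2), 10 * log(2), tolerance = 1e-12)
  expect_equal(firing_rate(p, 2), 1 / (10 * log(2)), tolerance = 1e-12)
  expect_equal(firing_rate(p, 2), 0.14427, tolerance = 1e-4)
  # sub-threshold drive: error from the interval, rate 0
  expect_error(interspike_interval(p, 0.5), "never fires")
  expect_identical(firing_rate(p, 1), 0)   # boundary R*I0 = V_th
  # vanishing threshold gives vanishing interval
  p2 <- lif_params(resistance = 1, tau_m = 10, threshold = 1e-9, dt = 0.01)
  expect_lt(interspike_interval(p2, 2), 1e-8)
  # interval is linear in tau at fixed drive
  p20 <- lif_params(resistance = 1, tau_m = 20, threshold = 1, dt = 0.02)
  expect_equal(interspike_interval(p20, 2), 2 * interspike_interval(p, 2),
               tolerance = 1e-12)
})

test_that("firing rate decreases strictly with the membrane time constant", {
  rates <- vapply(1:100, function(tau)
    firing_rate(lif_params(resistance = 1, tau_m = tau, threshold = 1,
                           dt = tau / 100), 2), numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("Euler simulation agrees with the closed forms", {
  tau <- 10
  p <- lif_params(resistance = 1, tau_m = tau, threshold = 1, dt = tau / 1000)
  # zero current: membrane stays at rest, no spikes
  sim0 <- lif_simulate(p, rep(0, 100))
  expect_true(all(sim0$trace$membrane == 0))
  expect_length(sim0$spikes, 0)
  # constant supra-threshold drive: empirical ISI within 1% of the closed form
  sim <- lif_simulate(p, rep(2, 8000))
  isi <- mean(diff(sim$spikes))
  expect_lt(abs(isi - interspike_interval(p, 2)) / interspike_interval(p, 2),
            0.01)
  # sub-threshold drive converges to R*I0, spikeless
  psub <- lif_params(resistance = 1, tau_m = tau, threshold = 5, dt = tau / 100)
  simsub <- lif_simulate(psub, rep(2, 5000))
  expect_length(simsub$spikes, 0)
  expect_equal(tail(simsub$trace$membrane, 1), 2, tolerance = 1e-6)
  # before the first spike the simulated membrane tracks the analytic
  # solution to within O(dt)
  pre <- sim$trace[sim$trace$time < sim$spikes[1], ]
  expect_lt(max(abs(pre$membrane - membrane_closed_form(p, 2, pre$time))),
            5 * p$dt)
  expect_error(lif_simulate(p, numeric(0)), "non-empty")
})

test_that("refractory period suppresses integration after a spike", {
  p <- lif_params(resistance = 1, tau_m = 10, threshold = 1, dt = 0.01)
  no_ref <- lif_simulate(p, rep(2, 4000))
  with_ref <- lif_simulate(p, rep(2, 4000), refractory = 5)
  expect_gt(length(no_ref$spikes), length(with_ref$spikes))
  expect_gte(min(diff(with_ref$spikes)), 5)
})

test_that("tau evolution matches the exponential rule and respects bounds", {
  r <- tau_rule(rate = 0.5, tau_init = 2, tau_bounds = c(0.1, 100),
                mode = "recurrent")
  expect_identical(evolve_tau(r, 2, 0), 2)           # exp(0) = 1
  expect_equal(evolve_tau(r, 2, 0.1), 2 * exp(0.05), tolerance = 1e-12)
  expect_equal(evolve_tau(r, 2, 0.1), 2.10254, tolerance = 1e-5)
  # any sequence of updates stays inside the bounds
  tau <- 2
  for (e in runif(50, 0, 20)) {
    tau <- evolve_tau(r, tau, e)
    expect_gte(tau, 0.1); expect_lte(tau, 100)
  }
  # anchored mode: rescales the initial value, so E = 0 restores tau_init
  ra <- tau_rule(rate = -0.3, tau_init = 8, tau_bounds = c(1, 100))
  drifted <- evolve_tau(ra, 8, 2)
  expect_lt(drifted, 8)
  expect_identical(evolve_tau(ra, drifted, 0), 8)
  expect_error(evolve_tau(ra, 8, NaN), "finite")
})

test_that("lif_params enforces tau = R*C and warns on coarse dt", {
  p <- lif_params(resistance = 2, capacitance = 5)
  expect_equal(p$tau_m, 10)
  expect_error(lif_params(resistance = 2, capacitance = 5, tau_m = 3), "equal")
  expect_error(lif_params(tau_m = 10, threshold = 0, reset_potential = 0),
               "exceed")
  expect_warning(lif_params(tau_m = 10, dt = 2), "coarse")
})
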