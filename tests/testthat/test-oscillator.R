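test_that("relative-phase flow evaluates the detuning-minus-sine field", {
  expect_equal(relative_phase_flow(0, 0, 1), 0)
  expect_equal(relative_phase_flow(pi / 2, 0.5, 1), -0.5)
  expect_equal(relative_phase_flow(c(0, pi), 2, 3), c(2, 2))
})

test_that("fixed points follow the arcsin closed form and vanish beyond the locking bound", {
  fp <- fixed_points(0, 1)
  expect_equal(fp$psi_star, c(0, pi))
  expect_equal(fp$stability, c("stable", "unstable"))
  fp <- fixed_points(0.5, 1)
  expect_equal(fp$psi_star[fp$stability == "stable"], pi / 6)
  expect_equal(fp$psi_star[fp$stability == "unstable"], 5 * pi / 6)
  expect_equal(nrow(fixed_points(1.5, 1)), 0)
  expect_equal(nrow(fixed_points(-2, 1.9)), 0)
})

test_that("full phase simulation matches direct integration of the relative-phase flow", {
  stim <- model_stimulus(120, duration = 30)
  for (dw in c(0.5, 1.5)) {
    sim <- simulate_fixed_detuning(stim, c = 1, delta_omega = dw,
                                   detune_at = 5)
    # oracle: adaptive integration of d(psi)/dt = dw - c sin(psi) from the
    # detuning onset (psi = 0 identically before it)
    t_post <- sim$t[sim$t >= 5]
    orc <- deSolve::ode(y = c(psi = 0), times = t_post,
                        func = function(t, y, p) list(dw - sin(y)),
                        parms = NULL, method = "ode45",
                        rtol = 1e-10, atol = 1e-12)
    expect_lt(max(abs(sim$psi[sim$t >= 5] - orc[, "psi"])), 1e-6)
  }
})

test_that("phase-locking occurs iff detuning does not exceed coupling strength", {
  stim <- model_stimulus(120, duration = 40)
  for (dw in c(0.25, 0.6, 0.95)) {      # |dw| < c: locks at asin(dw)
    sim <- simulate_fixed_detuning(stim, c = 1, delta_omega = dw, detune_at = 5)
    expect_equal(sim$psi[length(sim$psi)], asin(dw), tolerance = 1e-3)
  }
  for (dw in c(1.1, 1.5, 3)) {          # |dw| > c: psi drifts without bound
    sim <- simulate_fixed_detuning(stim, c = 1, delta_omega = dw, detune_at = 5)
    expect_gt(max(sim$psi), 2 * pi)
  }
})

test_that("event detection recovers closed-form crossing times and converges in dt", {
  t <- seq(0, 3, by = 0.001)
  ev <- detect_events(t, 4 * pi * t)
  expect_equal(ev, seq(0, 3, by = 0.5), tolerance = 1e-9)
  expect_length(detect_events(t, rep(1, length(t))), 0)
  # halving dt moves smooth-trajectory event times by < 1e-6 s
  stim <- model_stimulus(120, duration = 20)
  s1 <- simulate_fixed_detuning(stim, c = 1, delta_omega = 0.5, dt = 0.001)
  s2 <- simulate_fixed_detuning(stim, c = 1, delta_omega = 0.5, dt = 0.0005)
  n <- min(length(s1$tap_times), length(s2$tap_times))
  expect_lt(max(abs(s1$tap_times[1:n] - s2$tap_times[1:n])), 1e-6)
})

test_that("without intention the context model stays in phase; with rho 0 it equals sine coupling", {
  stim <- model_stimulus(120, duration = 20)
  p0 <- context_params(lambda_pre = 0, lambda_post = 0)
  sim <- simulate_context_model(p0, stim)
  expect_lt(max(abs(sim$psi)), 1e-9)
  expect_lt(max(abs(sim$omega - stim$omega0)), 1e-9)
  # gamma = lambda = 0, rho = 0 reduces the phase equation to the
  # fixed-detuning model with zero detuning
  pr <- context_params(gamma = 0, lambda_pre = 0, lambda_post = 0, rho = 0,
                       c = 1)
  sc <- simulate_context_model(pr, stim)
  sf <- simulate_fixed_detuning(stim, c = 1, delta_omega = 0)
  expect_lt(max(abs(sc$phi - sf$phi)), 1e-9)
})

test_that("the three intention regimes reproduce one, zero, and many laps", {
  stim <- model_stimulus(120)
  laps <- vapply(regime_deltas, function(D) {
    count_sim_laps(simulate_context_model(context_params(Delta = D), stim))
  }, integer(1))
  expect_identical(laps[["successful"]], 1L)
  expect_identical(laps[["incomplete"]], 0L)
  expect_gte(laps[["unsuccessful"]], 2L)
})

test_that("halving the step changes the final relative phase negligibly in every regime", {
  stim <- model_stimulus(120, duration = 30)
  for (D in regime_deltas) {
    s1 <- simulate_context_model(context_params(Delta = D), stim, dt = 0.001)
    s2 <- simulate_context_model(context_params(Delta = D), stim, dt = 0.0005)
    expect_lt(abs(s1$psi[length(s1$psi)] - s2$psi[length(s2$psi)]), 1e-4)
  }
})

test_that("simulated taps classified by the experimental pipeline agree on lap count", {
  stim <- model_stimulus(120)
  for (D in regime_deltas) {
    sim <- simulate_context_model(context_params(Delta = D), stim)
    expect_identical(classify_trial(sim_to_trial(sim))$laps,
                     count_sim_laps(sim))
  }
})

test_that("coarse steps and bad stimuli are rejected", {
  stim <- model_stimulus(120, duration = 10)
  expect_error(simulate_fixed_detuning(stim, dt = 0.1), "coarse")
  expect_error(simulate_fixed_detuning(stim, dt = -1), "positive")
  expect_error(stimulus_spec(0, 60, 5), "tempo")
  expect_error(stimulus_spec(120, 60, 70), "cue_time")
})
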