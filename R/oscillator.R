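#' Parameters of the context-dependent phasing model
#'
#' Bundles the parameters of the two-equation model
#' \deqn{d\phi/dt = \omega + c f(\phi, \theta, \rho)}
#' \deqn{d\omega/dt = \gamma f(\phi, \theta, \rho) -
#'       \lambda g(\phi, \theta, \rho) (\dot\psi - \Delta)}
#' where \eqn{f} is the pulse coupling ([coupling_f()]) and \eqn{g} the
#' context gate ([gating_g()]). `c` is phase attraction (involuntary),
#' `gamma` pulls the natural frequency toward the stimulus frequency
#' (synchronization), and the `lambda` term biases it away so that the
#' relative phase advances at the target rate `Delta` (the intended
#' gradualness of phasing). The bias strength switches from `lambda_pre`
#' (0 during initial in-phase tapping) to `lambda_post` at the cue.
#'
#' Defaults are the replication values used for all model experiments:
#' `c = 30`, `gamma = 15`, `lambda_post = 3`, `psi_theta = pi/2`.
#' `rho = NULL` requests per-tempo calibration to a 100 ms pulse FWHM at
#' simulation time.
#'
#' @param c Coupling strength (1/s), `>= 0`.
#' @param gamma Frequency adaptation rate (1/s), `>= 0`.
#' @param lambda_pre,lambda_post Intentional bias strength before/after the
#'   cue (dimensionless).
#' @param Delta Target change rate of relative phase (rad/s).
#' @param psi_theta Gate-switching threshold on unwrapped relative phase
#'   (rad).
#' @param rho Pulse-width parameter in `[0, 1)`, or `NULL` to calibrate for
#'   the stimulus tempo at 100 ms FWHM.
#' @return A `context_params` list.
#' @export
context_params <- function(c = 30, gamma = 15, lambda_pre = 0,
                           lambda_post = 3, Delta = 1, psi_theta = pi / 2,
                           rho = NULL) {
  stopifnot(c >= 0, gamma >= 0, is.numeric(Delta), length(Delta) == 1)
  if (!is.null(rho)) check_rho(rho)
  structure(
    list(c = c, gamma = gamma, lambda_pre = lambda_pre,
         lambda_post = lambda_post, Delta = Delta, psi_theta = psi_theta,
         rho = rho),
    class = "context_params"
  )
}

#' Instantaneous flow of the relative phase under sine coupling
#'
#' For the sine-coupled oscillator the relative phase \eqn{\psi = \phi -
#' \theta} obeys the autonomous flow \eqn{d\psi/dt = \Delta\omega - c
#' \sin\psi} (the Adler equation).
#'
#' @param psi Relative phase (rad), vectorized.
#' @param delta_omega Frequency detuning \eqn{\omega - \omega_0} (rad/s).
#' @param c Coupling strength (1/s).
#' @return `d(psi)/dt` in rad/s.
#' @export
relative_phase_flow <- function(psi, delta_omega, c) {
  delta_omega - c * sin(psi)
}

#' Fixed points of the relative-phase flow
#'
#' Roots of \eqn{\Delta\omega - c \sin\psi = 0} on \eqn{(-\pi, \pi]} with
#' their stability (sign of \eqn{-c\cos\psi^*}). No fixed point exists when
#' `|delta_omega| > c`: the oscillator cannot phase-lock and the relative
#' phase drifts monotonically.
#'
#' @inheritParams relative_phase_flow
#' @return A data frame with columns `psi_star` (rad) and `stability`
#'   (`"stable"`/`"unstable"`); zero rows if no fixed point exists.
#' @export
fixed_points <- function(delta_omega, c) {
  stopifnot(c > 0)
  empty <- data.frame(psi_star = numeric(0), stability = character(0),
                      stringsAsFactors = FALSE)
  if (abs(delta_omega) > c) return(empty)
  s <- asin(delta_omega / c)          # stable branch (cos >= 0)
  u <- pi - s                         # unstable branch
  u <- ((u + pi) %% (2 * pi)) - pi    # wrap to (-pi, pi]
  if (u <= -pi) u <- u + 2 * pi
  if (abs(delta_omega) == c) {        # saddle-node: single half-stable point
    return(data.frame(psi_star = s, stability = "unstable",
                      stringsAsFactors = FALSE))
  }
  data.frame(psi_star = c(s, u),
             stability = c("stable", "unstable"),
             stringsAsFactors = FALSE)
}

#' Simulate the sine-coupled oscillator with fixed frequency detuning
#'
#' Integrates \eqn{d\phi/dt = \omega + c\sin(\theta - \phi)} with
#' \eqn{\theta = \omega_0 t}, starting in phase (\eqn{\phi(0) = 0},
#' \eqn{\omega = \omega_0}); at `detune_at` the natural frequency steps to
#' \eqn{\omega_0 + \Delta\omega}, emulating a fixed intention to speed up.
#' Uses a fixed-step classical Runge–Kutta scheme so runs are bit-for-bit
#' reproducible.
#'
#' @param stim A [stimulus_spec()]; [model_stimulus()] defaults suit model
#'   runs.
#' @param c Coupling strength (1/s).
#' @param delta_omega Frequency detuning applied after `detune_at` (rad/s).
#' @param detune_at Time the detuning is introduced (s); defaults to the
#'   stimulus cue time.
#' @param dt Integration step (s), default 0.001. Must resolve the period
#'   (`dt <= period / 200`).
#' @return A `phasing_sim` object: `t`, `phi` (unwrapped oscillator phase),
#'   `omega` (natural frequency), `psi` (unwrapped relative phase),
#'   `tap_times`, `tick_times`, plus the stimulus and parameters.
#' @export
simulate_fixed_detuning <- function(stim, c = 1, delta_omega = 0,
                                    detune_at = stim$cue_time, dt = 0.001) {
  check_dt(dt, stim)
  raw <- fixed_rk4(stim$omega0, c, delta_omega, detune_at, stim$duration, dt)
  finish_sim(raw, stim, model = "fixed_detuning",
             params = list(c = c, delta_omega = delta_omega,
                           detune_at = detune_at, dt = dt))
}

#' Simulate the context-dependent phasing model
#'
#' Integrates the coupled phase/frequency system (see [context_params()])
#' from an in-phase start (\eqn{\phi(0) = 0}, \eqn{\omega(0) = \omega_0}).
#' The intentional bias switches from `lambda_pre` to `lambda_post` exactly
#' at the stimulus cue time, which must fall on the integration grid. The
#' relative-phase rate entering the bias term is eliminated through the
#' identity \eqn{\dot\psi = \omega + c f - \omega_0}, giving an explicit
#' system integrated with fixed-step classical Runge–Kutta.
#'
#' Taps are emitted where the wrapped oscillator phase crosses zero upward;
#' ticks where the stimulus phase does.
#'
#' @param params A [context_params()] object.
#' @param stim A [stimulus_spec()]; [model_stimulus()] gives the 60 s / cue
#'   5 s protocol used in model experiments.
#' @param dt Integration step (s), default 0.001.
#' @return A `phasing_sim` object (see [simulate_fixed_detuning()]).
#' @examples
#' stim <- model_stimulus(120)
#' sim <- simulate_context_model(context_params(Delta = 1), stim)
#' count_sim_laps(sim)   # 1: successful phasing
#' @export
simulate_context_model <- function(params, stim, dt = 0.001) {
  stopifnot(inherits(params, "context_params"), inherits(stim, "stimulus_spec"))
  check_dt(dt, stim)
  rho <- params$rho
  if (is.null(rho)) rho <- calibrate_rho(stim$omega0)
  if (abs(stim$cue_time / dt - round(stim$cue_time / dt)) > 1e-9) {
    stop("cue_time must fall on the integration grid (a multiple of dt)")
  }
  raw <- context_rk4(stim$omega0, params$c, params$gamma, params$lambda_pre,
                     params$lambda_post, params$Delta, params$psi_theta,
                     rho, stim$cue_time, stim$duration, dt)
  p <- params
  p$rho <- rho
  p$dt <- dt
  finish_sim(raw, stim, model = "context", params = unclass(p))
}

finish_sim <- function(raw, stim, model, params) {
  psi <- raw$phi - stim$omega0 * raw$t
  structure(
    list(t = raw$t, phi = raw$phi, omega = raw$omega, psi = psi,
         tap_times = detect_events(raw$t, raw$phi),
         tick_times = detect_events(raw$t, stim$omega0 * raw$t),
         stim = stim, model = model, params = params),
    class = "phasing_sim"
  )
}

check_dt <- function(dt, stim) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("dt must be a positive number")
  }
  if (dt > 0.005 * stim$period) {
    stop("dt too coarse: need dt <= 0.005 * period = ",
         signif(0.005 * stim$period, 4), " s to resolve events")
  }
  invisible(dt)
}

#' Locate upward phase crossings of multiples of 2*pi
#'
#' Event extraction from a sampled unwrapped phase trajectory: an event is
#' recorded each time the phase crosses an integer multiple of \eqn{2\pi}
#' from below (equivalently, the wrapped phase crosses zero upward), with
#' the crossing time located by linear interpolation between the bracketing
#' samples. A sample lying exactly on a multiple at the start of the grid
#' counts as an event (the in-phase initial tap).
#'
#' @param t Sample times (uniform grid, seconds).
#' @param phase Unwrapped phase at `t` (rad).
#' @return Numeric vector of event times (s), increasing.
#' @export
detect_events <- function(t, phase) {
  stopifnot(length(t) == length(phase), length(t) >= 1)
  lev <- floor(phase / (2 * pi) + 1e-12)
  ev <- numeric(0)
  if (abs(phase[1] - round(phase[1] / (2 * pi)) * 2 * pi) < 1e-12) {
    ev <- t[1]
  }
  up <- which(diff(lev) >= 1)
  for (i in up) {
    for (k in (lev[i] + 1):lev[i + 1]) {
      target <- 2 * pi * k
      # linear interpolation inside the bracketing step
      w <- (target - phase[i]) / (phase[i + 1] - phase[i])
      ev <- c(ev, t[i] + w * (t[i + 1] - t[i]))
    }
  }
  unique(ev)
}

#' Count phasing laps in a simulation
#'
#' Number of complete \eqn{2\pi}-rounds of the unwrapped relative phase
#' between the cue and the end of the run, evaluated at tap events:
#' `floor((max psi_at_taps - psi_at_cue) / 2pi)`, floored at zero. One lap
#' is a successful phasing run, more than one unsuccessful, zero incomplete.
#'
#' @param sim A `phasing_sim` from [simulate_context_model()] or
#'   [simulate_fixed_detuning()].
#' @return Integer lap count.
#' @export
count_sim_laps <- function(sim) {
  stopifnot(inherits(sim, "phasing_sim"))
  stim <- sim$stim
  psi_cue <- stats::approx(sim$t, sim$psi, xout = stim$cue_time)$y
  taps <- sim$tap_times[sim$tap_times >= stim$cue_time]
  if (length(taps) == 0) return(0L)
  psi_taps <- stats::approx(sim$t, sim$psi, xout = taps)$y
  max(0L, as.integer(floor((max(psi_taps) - psi_cue) / (2 * pi) + 1e-9)))
}

#' Taps per phasing lap of a simulation
#'
#' The model analogue of the experimental taps-per-lap statistic. A
#' deterministic simulation holds the relative phase exactly at the lock
#' value before the cue, so the experiment's empirical in-phase range
#' (which gets its width from motor noise) degenerates to a point. The
#' phasing window is therefore bounded by the lock values themselves: it
#' opens after the last tap still at the pre-cue relative phase (within
#' `tol`) and closes at the first tap whose relative phase has advanced by
#' `laps` full cycles. Taps strictly inside, divided by `laps`, give the
#' gradualness statistic; slow creep out of the in-phase basin counts as
#' phasing, exactly as it does in noisy human trials.
#'
#' @param sim A `phasing_sim` from [simulate_context_model()].
#' @param laps Lap count; defaults to [count_sim_laps()].
#' @param tol Tolerance (rad) for "still at the pre-cue phase".
#' @return Taps per lap (numeric), or `NA` when `laps == 0`.
#' @export
sim_taps_per_lap <- function(sim, laps = count_sim_laps(sim), tol = 1e-6) {
  stopifnot(inherits(sim, "phasing_sim"))
  if (is.na(laps) || laps < 1) return(NA_real_)
  stim <- sim$stim
  psi_cue <- stats::approx(sim$t, sim$psi, xout = stim$cue_time)$y
  taps <- sim$tap_times
  psi <- stats::approx(sim$t, sim$psi, xout = taps)$y
  at_lock <- which(psi <= psi_cue + tol)
  start <- if (length(at_lock)) taps[max(at_lock)] else stim$cue_time
  arrived <- which(psi >= psi_cue + 2 * pi * laps - tol & taps > start)
  end <- if (length(arrived)) taps[arrived[1]] else taps[length(taps)]
  sum(taps > start & taps < end) / laps
}

#' @export
print.phasing_sim <- function(x, ...) {
  cat(sprintf("<phasing_sim: %s model, %g BPM, %g s, dt = %g s>\n",
              x$model, x$stim$tempo_bpm, x$stim$duration, x$params$dt))
  cat(sprintf("  taps: %d, ticks: %d, final unwrapped relative phase: %.3f rad\n",
              length(x$tap_times), length(x$tick_times),
              x$psi[length(x$psi)]))
  cat(sprintf("  laps after cue: %d\n", count_sim_laps(x)))
  invisible(x)
}

#' @export
plot.phasing_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  taps <- x$tap_times
  psi_taps <- stats::approx(x$t, x$psi, xout = taps)$y
  graphics::plot(taps, psi_taps / (2 * pi), pch = 16, cex = 0.5,
                 xlab = "time (s)", ylab = "relative phase / 2π", ...)
  graphics::abline(v = x$stim$cue_time, lty = 2)
  graphics::plot(x$t, x$omega / (2 * pi), type = "l",
                 xlab = "time (s)", ylab = "natural frequency (Hz)")
  graphics::abline(h = x$stim$omega0 / (2 * pi), lty = 3)
  invisible(x)
}

#' Extract the tap events of a simulation as a tapping trial
#'
#' Bridges the model and the experimental pipeline: the simulated tap times
#' become a [tap_trial()] that [classify_trial()] can score exactly like a
#' human trial.
#'
#' @param sim A `phasing_sim`.
#' @param trial_id Identifier for the resulting trial.
#' @return A [tap_trial()] object.
#' @export
sim_to_trial <- function(sim, trial_id = "sim") {
  stopifnot(inherits(sim, "phasing_sim"))
  tap_trial(trial_id = trial_id, tempo_bpm = sim$stim$tempo_bpm,
            cue_time = sim$stim$cue_time, tap_times = sim$tap_times,
            first_beat_time = sim$stim$first_beat_time)
}
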