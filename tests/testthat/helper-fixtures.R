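# Shared fixtures: trials built by inverting the relative-phase definition
# tap by tap (t_n = m_n - psi_n * T / 2pi), independently of the package's
# generator, so analyzer tests do not lean on generator code paths.

# A phase_series object from raw wrapped values (times default to 1 s
# apart); set unwrapped = TRUE when the values are already unwrapped.
make_series <- function(psi, tap_times = seq_along(psi), unwrapped = FALSE) {
  structure(
    list(tap_times = tap_times,
         psi_wrapped = if (unwrapped) psi - 2 * pi * round(psi / (2 * pi))
                       else psi,
         psi_unwrapped = if (unwrapped) psi
                         else rep(NA_real_, length(psi))),
    class = "phase_series"
  )
}

# A tap_trial whose analysis recovers the given unwrapped psi trajectory,
# one tap per beat starting at beat 1.
trial_from_psi <- function(psi, tempo_bpm = 120, cue_time = 7,
                           first_beat = 0, id = "fixture") {
  T <- 60 / tempo_bpm
  cue <- first_beat + round((cue_time - first_beat) / T) * T
  times <- first_beat + seq_along(psi) * T - psi * T / (2 * pi)
  tap_trial(trial_id = id, tempo_bpm = tempo_bpm, cue_time = cue,
            tap_times = times, first_beat_time = first_beat)
}

# Unwrapped psi trajectory for a clean ramp trial: pre-cue plateau, monotone
# ramp over k_ramp taps through `laps` cycles, then in-phase tail.
ramp_psi <- function(laps = 1, n_pre = 14, k_ramp = 15, n_tail = 4,
                     asynchrony = 0.2) {
  ramp <- asynchrony + 2 * pi * laps * seq_len(k_ramp) / (k_ramp + 1)
  c(rep(asynchrony, n_pre), ramp, rep(asynchrony + 2 * pi * laps, n_tail))
}

regime_deltas <- c(successful = 1, unsuccessful = 3, incomplete = 0.5)

# A bare trial_outcome record (bypasses the pipeline) for summary tests.
new_outcome <- function(id, tempo, laps, outcome, tpl = NA_real_,
                        subtype = "none") {
  structure(
    list(trial_id = id, tempo_bpm = tempo, laps = laps, outcome = outcome,
         subtype = subtype, window_start = NA_real_, window_end = NA_real_,
         taps_in_window = if (is.na(tpl)) NA_integer_
                          else as.integer(round(tpl * max(laps, 1))),
         taps_per_lap = tpl),
    class = "trial_outcome"
  )
}

all_templates <- function(jitter_sd = 0) {
  list(
    trajectory_template("successful", jitter_sd = jitter_sd),
    trajectory_template("unsuccessful", laps = 2, jitter_sd = jitter_sd),
    trajectory_template("unsuccessful", laps = 4, jitter_sd = jitter_sd),
    trajectory_template("incomplete", subtype = "trapped", jitter_sd = jitter_sd),
    trajectory_template("incomplete", subtype = "return", jitter_sd = jitter_sd),
    trajectory_template("incomplete", subtype = "halfway", jitter_sd = jitter_sd),
    trajectory_template("incomplete", subtype = "backward", jitter_sd = jitter_sd)
  )
}
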