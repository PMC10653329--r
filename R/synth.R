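#' Template for a synthetic phasing trajectory
#'
#' Describes the ground-truth trajectory of a synthetic tapping trial:
#' which outcome it should realize, how many taps make up the phasing
#' excursion, the pre-cue tap-beat asynchrony, and the motor-noise level.
#' The generator places taps so that the analysis pipeline, run on the
#' noise-free trial, recovers exactly these labels.
#'
#' @param outcome Target outcome: `"successful"`, `"unsuccessful"`, or
#'   `"incomplete"`.
#' @param laps Target lap count for unsuccessful templates (`>= 2`);
#'   forced to 1 / 0 for successful / incomplete.
#' @param subtype Incomplete subtype: `"trapped"`, `"return"`, `"halfway"`,
#'   or `"backward"`. Only valid with `outcome = "incomplete"`.
#' @param n_phasing_taps Taps in the phasing excursion (default 20). For
#'   lap-making templates must exceed `2 * laps` so no single tap advances
#'   the phase by more than \eqn{\pi} (which would defeat unwrapping, as it
#'   would in human data).
#' @param n_final_taps In-phase taps appended after the excursion
#'   (default 4).
#' @param asynchrony_mean Mean pre-cue relative phase (rad, default 0.2:
#'   taps slightly ahead of the beat, the typical negative mean asynchrony).
#' @param jitter_sd Gaussian tap-time jitter SD as a fraction of the
#'   metronome period (default 0.02); truncated at 3 SD so taps never
#'   reorder.
#' @return A `trajectory_template` object.
#' @export
trajectory_template <- function(outcome = c("successful", "unsuccessful",
                                            "incomplete"),
                                laps = 2, subtype = "return",
                                n_phasing_taps = 20, n_final_taps = 4,
                                asynchrony_mean = 0.2, jitter_sd = 0.02) {
  outcome <- match.arg(outcome)
  if (outcome == "incomplete") {
    subtype <- match.arg(subtype, SUBTYPE_LEVELS[1:4])
  } else {
    subtype <- "none"
  }
  laps <- switch(outcome, successful = 1L, incomplete = 0L,
                 unsuccessful = as.integer(laps))
  if (outcome == "unsuccessful" && laps < 2) {
    stop("unsuccessful templates need laps >= 2")
  }
  stopifnot(jitter_sd >= 0, n_phasing_taps >= 1)
  if (laps >= 1 && n_phasing_taps <= 2 * laps) {
    stop("n_phasing_taps must exceed 2 * laps to keep per-tap phase ",
         "increments below pi")
  }
  structure(
    list(outcome = outcome, laps = laps, subtype = subtype,
         n_phasing_taps = as.integer(n_phasing_taps),
         n_final_taps = as.integer(n_final_taps),
         asynchrony_mean = asynchrony_mean, jitter_sd = jitter_sd),
    class = "trajectory_template"
  )
}

# Monotone cubic ramp (smoothstep) from 0 to 1.
smoothstep <- function(u) u * u * (3 - 2 * u)

#' Generate a synthetic tapping trial with known ground truth
#'
#' Builds a target unwrapped relative-phase trajectory — a pre-cue plateau
#' at the template asynchrony, then an excursion realizing the target
#' outcome (a smoothstep ramp through `laps` full cycles; or the
#' subtype-specific shape: bounded plateau for trapped, rise-and-fall for
#' return, rise-and-hold for halfway, monotone descent for backward) — and
#' inverts the relative-phase definition tap by tap,
#' \eqn{t_n = m_n - \psi_n T / 2\pi} with \eqn{m_n} the intended beat, so
#' the analysis pipeline recovers the target phases exactly at zero jitter.
#' Gaussian jitter of SD `jitter_sd * T` (truncated at ±3 SD) is then added
#' to the tap times.
#'
#' @param template A [trajectory_template()].
#' @param stim A [stimulus_spec()]; [make_stimulus()] gives the experiment's
#'   2-minute / cue-at-7-s protocol.
#' @param seed Integer seed for the jitter RNG (one generator per trial).
#' @return List with `trial` (a [tap_trial()]) and `truth` (list:
#'   `outcome`, `subtype`, `laps`, `taps_in_window`).
#' @examples
#' tr <- generate_trial(trajectory_template("successful", jitter_sd = 0),
#'                      make_stimulus(120), seed = 1)
#' classify_trial(tr$trial)$outcome
#' @export
generate_trial <- function(template, stim, seed = 1L) {
  stopifnot(inherits(template, "trajectory_template"),
            inherits(stim, "stimulus_spec"))
  T <- stim$period
  a <- template$asynchrony_mean
  K <- template$n_phasing_taps
  Fn <- template$n_final_taps

  cue_idx <- round((stim$cue_time - stim$first_beat_time) / T)
  n_pre <- cue_idx               # taps on beats 1 .. cue beat
  psi_pre <- rep(a, n_pre)

  psi_exc <- switch(
    template$outcome,
    successful = a + 2 * pi * smoothstep((1:K) / (K + 1)),
    unsuccessful = a + 2 * pi * template$laps * smoothstep((1:K) / (K + 1)),
    incomplete = switch(
      template$subtype,
      trapped = rep(a, K),
      return = a + pi * sin(pi * (1:K) / (K + 1)),     # rise to ~pi, fall back
      halfway = a + pi * smoothstep(pmin(1, (1:K) / ceiling(K / 2))),
      backward = a - pi * smoothstep((1:K) / K)
    )
  )
  psi_fin <- rep(a + 2 * pi * template$laps, Fn)
  if (template$outcome == "incomplete" &&
      template$subtype %in% c("halfway", "backward")) {
    psi_fin <- rep(psi_exc[K], Fn)   # hold the final excursion level
  }
  psi <- c(psi_pre, psi_exc, psi_fin)
  if (length(psi) > 1 && max(abs(diff(psi))) >= pi) {
    stop("infeasible template: per-tap phase increment reaches pi")
  }

  idx <- seq_along(psi)            # intended beat index, one tap per beat
  times <- stim$first_beat_time + idx * T - psi * T / (2 * pi)
  if (max(times) > stim$duration) {
    stop("infeasible template: taps exceed the stimulus duration")
  }
  if (template$jitter_sd > 0) {
    set.seed(as.integer(seed))
    sdev <- template$jitter_sd * T
    j <- rnorm(length(times), 0, sdev)
    j <- pmin(pmax(j, -3 * sdev), 3 * sdev)
    times <- times + j
  }
  trial <- tap_trial(trial_id = sprintf("synth_%s_%d", template$outcome, seed),
                     tempo_bpm = stim$tempo_bpm, cue_time = stim$cue_time,
                     tap_times = times,
                     first_beat_time = stim$first_beat_time)
  truth <- list(outcome = template$outcome, subtype = template$subtype,
                laps = template$laps,
                taps_in_window = if (template$laps >= 1) K else NA_integer_)
  list(trial = trial, truth = truth)
}

#' Generate a synthetic dataset of phasing trials
#'
#' Emulates the experiment's design — a fixed number of trials per
#' metronome tempo — with a configurable mix of target outcomes. Templates
#' from `mix` are cycled within each tempo; each trial gets its own seed
#' derived deterministically from `seed`, so the dataset is reproducible.
#'
#' @param n_per_tempo Trials per tempo (the experiment used 3).
#' @param tempi Metronome tempi in BPM (default `seq(80, 140, 10)`).
#' @param mix List of [trajectory_template()]s cycled across trials
#'   (default: one successful, one unsuccessful, one incomplete-return).
#' @param seed Base integer seed.
#' @param stim_fun Function mapping a tempo to a [stimulus_spec()]
#'   (default [make_stimulus()]).
#' @return List of `list(trial, truth)` pairs, length
#'   `n_per_tempo * length(tempi)`.
#' @export
generate_dataset <- function(n_per_tempo = 3, tempi = seq(80, 140, by = 10),
                             mix = list(
                               trajectory_template("successful"),
                               trajectory_template("unsuccessful", laps = 2),
                               trajectory_template("incomplete",
                                                   subtype = "return")),
                             seed = 1L, stim_fun = make_stimulus) {
  stopifnot(n_per_tempo >= 1, length(tempi) >= 1, length(mix) >= 1)
  out <- vector("list", n_per_tempo * length(tempi))
  k <- 0L
  for (tp in tempi) {
    stim <- stim_fun(tp)
    for (i in seq_len(n_per_tempo)) {
      k <- k + 1L
      tmpl <- mix[[(k - 1L) %% length(mix) + 1L]]
      g <- generate_trial(tmpl, stim, seed = as.integer(seed) + k)
      g$trial$trial_id <- sprintf("t%03d_%dbpm", k, tp)
      out[[k]] <- g
    }
  }
  out
}

#' Flatten generated trials to the tap-table CSV schema
#'
#' @param dataset Output of [generate_dataset()] (or a list of
#'   `list(trial, truth)` pairs).
#' @return List with `taps` (one row per tap: `trial_id`, `tempo_bpm`,
#'   `first_beat_time_s`, `cue_time_s`, `tap_time_s`) and `truth` (one row
#'   per trial).
#' @export
dataset_to_tables <- function(dataset) {
  taps <- do.call(rbind, lapply(dataset, function(g) {
    tr <- g$trial
    data.frame(trial_id = tr$trial_id, tempo_bpm = tr$tempo_bpm,
               first_beat_time_s = tr$first_beat_time,
               cue_time_s = tr$cue_time, tap_time_s = tr$tap_times,
               stringsAsFactors = FALSE)
  }))
  truth <- do.call(rbind, lapply(dataset, function(g) {
    data.frame(trial_id = g$trial$trial_id, outcome = g$truth$outcome,
               subtype = g$truth$subtype, laps = g$truth$laps,
               stringsAsFactors = FALSE)
  }))
  list(taps = taps, truth = truth)
}
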