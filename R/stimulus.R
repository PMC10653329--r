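#' Convert tempo in BPM to angular frequency
#'
#' @param tempo_bpm Tempo in beats per minute.
#' @return Angular frequency in rad/s, `2 * pi * tempo_bpm / 60`.
#' @export
bpm_to_omega <- function(tempo_bpm) 2 * pi * tempo_bpm / 60

#' Metronome stimulus specification
#'
#' Describes a metronome stimulus: tempo, cue time (when the instruction to
#' begin phasing takes effect), total duration, and the time of the first
#' beat (the origin of the beat grid). The cue is snapped to the nearest
#' beat, mirroring a cue sound that coincides with a metronome beat.
#'
#' @param tempo_bpm Tempo, beats/min (`> 0`).
#' @param duration Stimulus duration, seconds.
#' @param cue_time Nominal cue time, seconds (`0 < cue_time < duration`);
#'   snapped to the nearest beat on the grid.
#' @param first_beat_time Time of the first beat, seconds (default 0).
#' @param snap_cue Snap `cue_time` to the beat grid (default `TRUE`).
#' @return A `stimulus_spec` object: list with `tempo_bpm`, `omega0`,
#'   `period`, `cue_time`, `duration`, `first_beat_time`.
#' @examples
#' stimulus_spec(120, duration = 120, cue_time = 7)
#' @export
stimulus_spec <- function(tempo_bpm, duration, cue_time,
                          first_beat_time = 0, snap_cue = TRUE) {
  if (!is.numeric(tempo_bpm) || length(tempo_bpm) != 1 || tempo_bpm <= 0) {
    stop("tempo_bpm must be a positive number")
  }
  stopifnot(length(duration) == 1, length(cue_time) == 1)
  period <- 60 / tempo_bpm
  if (snap_cue) {
    cue_time <- first_beat_time +
      round((cue_time - first_beat_time) / period) * period
  }
  if (!(cue_time > first_beat_time && cue_time < duration)) {
    stop("cue_time must lie strictly between first_beat_time and duration")
  }
  structure(
    list(tempo_bpm = tempo_bpm, omega0 = bpm_to_omega(tempo_bpm),
         period = period, cue_time = cue_time, duration = duration,
         first_beat_time = first_beat_time),
    class = "stimulus_spec"
  )
}

#' Experiment-style metronome stimulus
#'
#' Stimulus with the structure used in the tapping experiment: a 2-minute
#' metronome at a tempo between 80 and 140 BPM with a cue sound coinciding
#' with a beat near 7 s after the first beat.
#'
#' @inheritParams stimulus_spec
#' @return A [stimulus_spec()] object.
#' @export
make_stimulus <- function(tempo_bpm, duration = 120, cue_time = 7) {
  stimulus_spec(tempo_bpm, duration = duration, cue_time = cue_time)
}

#' Model-run metronome stimulus
#'
#' Stimulus defaults used for model simulations: a 60 s horizon with the
#' intention switch (cue) at 5 s. Long enough for every modeled regime to
#' settle while keeping parameter sweeps fast. Unlike the experiment's
#' bell sound, the model's cue is only the time the bias strength switches,
#' so it is not snapped to the beat grid (it must lie on the integration
#' grid instead).
#'
#' @inheritParams stimulus_spec
#' @return A [stimulus_spec()] object.
#' @export
model_stimulus <- function(tempo_bpm, duration = 60, cue_time = 5) {
  stimulus_spec(tempo_bpm, duration = duration, cue_time = cue_time,
                snap_cue = FALSE)
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "Metronome stimulus: %g BPM (period %.4f s), %g s long, cue at %g s\n",
    x$tempo_bpm, x$period, x$duration, x$cue_time))
  invisible(x)
}

#' Beat times of a stimulus
#'
#' @param stim A [stimulus_spec()] object.
#' @return Numeric vector of beat (tick) times within `[first_beat_time,
#'   duration]`.
#' @export
beat_times <- function(stim) {
  seq(stim$first_beat_time, stim$duration, by = stim$period)
}
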