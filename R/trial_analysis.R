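#' A finger-tapping trial against a metronome
#'
#' Container for one trial: the metronome grid (tempo, first-beat time), the
#' cue time after which the participant is to begin phasing, and the ordered
#' tap timestamps.
#'
#' @param trial_id Trial identifier (character scalar).
#' @param tempo_bpm Metronome tempo, beats/min.
#' @param cue_time Cue time (s), `> first_beat_time`.
#' @param tap_times Strictly increasing tap timestamps (s).
#' @param first_beat_time Time of the first metronome beat (s), the origin
#'   of the beat grid (default 0).
#' @return A `tap_trial` object.
#' @export
tap_trial <- function(trial_id, tempo_bpm, cue_time, tap_times,
                      first_beat_time = 0) {
  stopifnot(length(trial_id) == 1, is.numeric(tempo_bpm), tempo_bpm > 0,
            is.numeric(tap_times))
  if (length(tap_times) && any(diff(tap_times) <= 0)) {
    stop("tap_times must be strictly increasing (trial ", trial_id, ")")
  }
  if (!(cue_time > first_beat_time)) {
    stop("cue_time must be after first_beat_time")
  }
  structure(
    list(trial_id = as.character(trial_id), tempo_bpm = tempo_bpm,
         period = 60 / tempo_bpm, cue_time = cue_time,
         tap_times = as.numeric(tap_times),
         first_beat_time = first_beat_time),
    class = "tap_trial"
  )
}

#' @export
print.tap_trial <- function(x, ...) {
  cat(sprintf("<tap_trial %s: %g BPM, %d taps, cue at %g s>\n",
              x$trial_id, x$tempo_bpm, length(x$tap_times), x$cue_time))
  invisible(x)
}

#' Relative phase of each tap against the nearest beat
#'
#' For tap time \eqn{t_n} and nearest metronome beat \eqn{m_n},
#' \eqn{\psi_n = 2\pi (m_n - t_n) / T} with metronome period \eqn{T}: the
#' relative phase is positive when the tap precedes the beat and lies in
#' \eqn{(-\pi, \pi]}. A tap exactly halfway between two beats is assigned to
#' the later beat, yielding \eqn{+\pi}.
#'
#' @param trial A [tap_trial()].
#' @return A `phase_series` object: list with `tap_times`, `psi_wrapped`,
#'   and `psi_unwrapped` (`NA` until [unwrap_series()] is applied).
#' @export
tap_relative_phase <- function(trial) {
  stopifnot(inherits(trial, "tap_trial"))
  if (length(trial$tap_times) == 0) stop("trial has no taps")
  T <- trial$period
  k <- (trial$tap_times - trial$first_beat_time) / T
  # nearest beat index; floor(k + 0.5) sends the halfway tie to the later
  # beat so that psi = +pi, keeping psi in (-pi, pi]
  m <- trial$first_beat_time + floor(k + 0.5) * T
  psi <- 2 * pi * (m - trial$tap_times) / T
  structure(
    list(tap_times = trial$tap_times, psi_wrapped = psi,
         psi_unwrapped = rep(NA_real_, length(psi))),
    class = "phase_series"
  )
}

#' Unwrap a relative-phase series
#'
#' Corrects successive jumps larger than \eqn{\pi} in magnitude by multiples
#' of \eqn{2\pi}, so the relative phase can grow continuously past \eqn{\pi}
#' toward \eqn{2\pi} and beyond instead of jumping down to \eqn{-\pi}; this
#' is what makes lap counting possible. Delegates to [signal::unwrap()],
#' which matches the conventional (MATLAB-style) unwrap.
#'
#' @param series A `phase_series` from [tap_relative_phase()].
#' @return The series with `psi_unwrapped` filled in.
#' @export
unwrap_series <- function(series) {
  stopifnot(inherits(series, "phase_series"))
  series$psi_unwrapped <- signal::unwrap(series$psi_wrapped)
  series
}

#' Initial in-phase range of a trial
#'
#' The range (minimum and maximum) of wrapped relative phase over the taps
#' in the second half of the pre-cue interval, taken per trial because mean
#' tap-beat asynchrony differs across individuals and tempi. The pre-cue
#' interval runs from the first tap to the cue; its second half is the
#' latter half by time.
#'
#' The range is undeterminable — and the trial noncompliant — when fewer
#' than `min_taps` taps fall in that half-interval or when the range width
#' exceeds `max_width` (the participant did not hold in-phase tapping).
#'
#' @param trial A [tap_trial()].
#' @param series Its [tap_relative_phase()] series (computed if missing).
#' @param min_taps Minimum taps required in the half-interval (default 3).
#' @param max_width Maximum tolerated range width in rad (default `pi/2`).
#' @return List with `lo`, `hi`, `width` (rad), or `NULL` if the range
#'   cannot be determined (noncompliant trial).
#' @export
initial_inphase_range <- function(trial, series = tap_relative_phase(trial),
                                  min_taps = 3, max_width = pi / 2) {
  stopifnot(inherits(trial, "tap_trial"))
  pre <- series$tap_times < trial$cue_time
  if (!any(pre)) return(NULL)
  t0 <- series$tap_times[which(pre)[1]]
  half_start <- t0 + (trial$cue_time - t0) / 2
  sel <- pre & series$tap_times >= half_start
  if (sum(sel) < min_taps) return(NULL)
  lo <- min(series$psi_wrapped[sel])
  hi <- max(series$psi_wrapped[sel])
  if (hi - lo > max_width) return(NULL)
  list(lo = lo, hi = hi, width = hi - lo)
}

#' Count phasing laps in a tapping trial
#'
#' Number of complete \eqn{2\pi}-rounds between the minimum initial relative
#' phase and the maximum unwrapped relative phase of the trial:
#' `floor((max(psi_unwrapped) - range$lo) / 2pi)`, floored at zero. A small
#' additive guard (1e-9) protects exact whole-lap trajectories from being
#' floored down by floating-point representation.
#'
#' @param series An unwrapped `phase_series` (see [unwrap_series()]).
#' @param range The [initial_inphase_range()] of the trial.
#' @return Integer lap count (`>= 0`).
#' @export
count_laps <- function(series, range) {
  stopifnot(inherits(series, "phase_series"), !is.null(range))
  if (anyNA(series$psi_unwrapped)) series <- unwrap_series(series)
  max(0L, as.integer(floor(
    (max(series$psi_unwrapped) - range$lo) / (2 * pi) + 1e-9)))
}

#' Phasing window of a trial
#'
#' The phasing window begins after the last tap inside the initial in-phase
#' range (before the phase first departs upward from it) and ends before the
#' first tap inside the final in-phase range — the initial range translated
#' up by `2 pi * laps`, since phasing lands back on the same attractor one
#' lap up. For zero-lap trials the window closes at the last tap. Taps
#' strictly inside the window are the phasing taps.
#'
#' @param series An unwrapped `phase_series`.
#' @param range The [initial_inphase_range()].
#' @param laps Lap count from [count_laps()].
#' @return List with `window_start`, `window_end` (s) and `taps_in_window`.
#' @export
phasing_window <- function(series, range, laps) {
  stopifnot(inherits(series, "phase_series"), !is.null(range))
  if (anyNA(series$psi_unwrapped)) series <- unwrap_series(series)
  psi <- series$psi_unwrapped
  tt <- series$tap_times
  eps <- 1e-9
  in_init <- psi >= range$lo - eps & psi <= range$hi + eps
  departed <- which(psi > range$hi + eps)
  # last tap still inside the initial range before the first upward
  # departure; if the phase never departs, the last in-range tap
  limit <- if (length(departed)) departed[1] else length(psi) + 1L
  before <- which(in_init & seq_along(psi) < limit)
  window_start <- if (length(before)) tt[max(before)] else tt[1]
  if (laps >= 1) {
    fin_lo <- range$lo + 2 * pi * laps
    fin_hi <- range$hi + 2 * pi * laps
    in_final <- which(psi >= fin_lo - eps & psi <= fin_hi + eps)
    window_end <- if (length(in_final)) tt[in_final[1]] else tt[length(tt)]
  } else {
    window_end <- tt[length(tt)]
  }
  inside <- tt > window_start & tt < window_end
  list(window_start = window_start, window_end = window_end,
       taps_in_window = sum(inside))
}

#' Subtype of an incomplete trial
#'
#' Distinguishes how a zero-lap trial failed, using the initial in-phase
#' range widened by one range width on each side (the extended band) and the
#' unwrapped relative phase of the taps after the cue:
#' \describe{
#'   \item{trapped}{all post-cue taps stay inside the extended band — the
#'     participant never escaped the in-phase attractor.}
#'   \item{backward}{the phase leaves the band downward and never exceeds it
#'     upward — phasing in the wrong direction.}
#'   \item{return}{the phase leaves upward but the final tap is back inside
#'     the extended band — an escape that fell back without reaching the
#'     goal.}
#'   \item{halfway}{the phase leaves upward and ends outside the band short
#'     of a full lap.}
#' }
#' Precedence trapped > backward > return > halfway resolves overlaps
#' deterministically.
#'
#' @param series An unwrapped `phase_series`.
#' @param range The [initial_inphase_range()].
#' @param cue_time Cue time (s).
#' @return One of `"trapped"`, `"return"`, `"halfway"`, `"backward"`, or
#'   `"none"` when there are no post-cue taps.
#' @export
classify_incomplete_subtype <- function(series, range, cue_time) {
  stopifnot(inherits(series, "phase_series"), !is.null(range))
  if (anyNA(series$psi_unwrapped)) series <- unwrap_series(series)
  post <- series$tap_times >= cue_time
  if (!any(post)) return("none")
  psi <- series$psi_unwrapped[post]
  eps <- 1e-9
  band_lo <- range$lo - range$width - eps
  band_hi <- range$hi + range$width + eps
  if (all(psi >= band_lo & psi <= band_hi)) return("trapped")
  above <- any(psi > band_hi)
  below <- any(psi < band_lo)
  if (below && !above) return("backward")
  final <- psi[length(psi)]
  if (final >= band_lo && final <= band_hi) return("return")
  "halfway"
}

#' Classify a tapping trial
#'
#' Runs the full pipeline on one trial: tap relative phase, unwrapping,
#' initial in-phase range, lap counting, phasing-window extraction, outcome
#' labeling, and — for incomplete trials — subtype assignment. Outcomes:
#' \describe{
#'   \item{successful}{exactly one phasing lap, as instructed.}
#'   \item{unsuccessful}{more than one lap (overshot the in-phase goal).}
#'   \item{incomplete}{no complete lap; see
#'     [classify_incomplete_subtype()].}
#'   \item{noncompliant}{in-phase tapping before the cue could not be
#'     established, so the initial range is undeterminable.}
#' }
#' The taps-per-lap statistic — phasing-window taps divided by laps — is the
#' gradualness measure; it is defined only for trials with at least one lap.
#'
#' @param trial A [tap_trial()].
#' @param min_precue_taps,noncompliance_width Passed to
#'   [initial_inphase_range()].
#' @return A `trial_outcome` object: list with `trial_id`, `tempo_bpm`,
#'   `laps`, `outcome`, `subtype`, `window_start`, `window_end`,
#'   `taps_in_window`, `taps_per_lap`.
#' @examples
#' stim <- make_stimulus(120)
#' tr <- generate_trial(trajectory_template("successful"), stim, seed = 1)
#' classify_trial(tr$trial)$outcome
#' @export
classify_trial <- function(trial, min_precue_taps = 3,
                           noncompliance_width = pi / 2) {
  stopifnot(inherits(trial, "tap_trial"))
  series <- unwrap_series(tap_relative_phase(trial))
  range <- initial_inphase_range(trial, series, min_taps = min_precue_taps,
                                 max_width = noncompliance_width)
  if (is.null(range)) {
    return(new_trial_outcome(trial, laps = NA_integer_,
                             outcome = "noncompliant", subtype = "none",
                             window_start = NA_real_, window_end = NA_real_,
                             taps_in_window = NA_integer_,
                             taps_per_lap = NA_real_))
  }
  laps <- count_laps(series, range)
  win <- phasing_window(series, range, laps)
  outcome <- if (laps == 1) "successful"
             else if (laps > 1) "unsuccessful"
             else "incomplete"
  subtype <- if (outcome == "incomplete") {
    classify_incomplete_subtype(series, range, trial$cue_time)
  } else "none"
  tpl <- if (laps >= 1) win$taps_in_window / laps else NA_real_
  new_trial_outcome(trial, laps = laps, outcome = outcome, subtype = subtype,
                    window_start = win$window_start,
                    window_end = win$window_end,
                    taps_in_window = win$taps_in_window, taps_per_lap = tpl)
}

new_trial_outcome <- function(trial, laps, outcome, subtype, window_start,
                              window_end, taps_in_window, taps_per_lap) {
  structure(
    list(trial_id = trial$trial_id, tempo_bpm = trial$tempo_bpm,
         laps = laps, outcome = outcome, subtype = subtype,
         window_start = window_start, window_end = window_end,
         taps_in_window = taps_in_window, taps_per_lap = taps_per_lap),
    class = "trial_outcome"
  )
}

#' @export
print.trial_outcome <- function(x, ...) {
  cat(sprintf("<trial_outcome %s: %s", x$trial_id, x$outcome))
  if (x$outcome == "incomplete") cat(sprintf(" (%s)", x$subtype))
  if (!is.na(x$laps)) cat(sprintf(", %d lap%s", x$laps,
                                  if (x$laps == 1) "" else "s"))
  if (!is.na(x$taps_per_lap)) cat(sprintf(", %.2f taps/lap", x$taps_per_lap))
  cat(">\n")
  invisible(x)
}

#' Collect trial outcomes into a data frame
#'
#' @param x A list of `trial_outcome` objects.
#' @param row.names,optional,... Standard [as.data.frame()] arguments,
#'   ignored.
#' @return Data frame with one row per trial.
#' @export
outcomes_to_df <- function(x) {
  stopifnot(length(x) > 0)
  do.call(rbind, lapply(x, function(o) {
    data.frame(trial_id = o$trial_id, tempo_bpm = o$tempo_bpm,
               laps = o$laps, outcome = o$outcome, subtype = o$subtype,
               taps_in_window = o$taps_in_window,
               taps_per_lap = o$taps_per_lap, stringsAsFactors = FALSE)
  }))
}

#' Summarize classified trials
#'
#' Descriptive summaries of a set of classified trials: per-tempo counts and
#' proportions of each outcome (proportions among non-noncompliant trials,
#' which are the analyzable ones), and mean/SD of taps per lap for the
#' successful and unsuccessful classes. These tables are the inputs for any
#' downstream inferential statistics.
#'
#' @param outcomes A list of `trial_outcome` objects or a data frame from
#'   [outcomes_to_df()].
#' @return List with `by_tempo` (data frame: tempo, counts, proportions) and
#'   `taps_per_lap` (data frame: outcome class, n, mean, sd).
#' @export
summarize_dataset <- function(outcomes) {
  df <- if (is.data.frame(outcomes)) outcomes else outcomes_to_df(outcomes)
  stopifnot(nrow(df) >= 1)
  tempi <- sort(unique(df$tempo_bpm))
  by_tempo <- do.call(rbind, lapply(tempi, function(tp) {
    d <- df[df$tempo_bpm == tp, ]
    n <- vapply(OUTCOME_LEVELS, function(o) sum(d$outcome == o), integer(1))
    n_ok <- sum(n[1:3])
    data.frame(tempo_bpm = tp,
               n_successful = n[[1]], n_unsuccessful = n[[2]],
               n_incomplete = n[[3]], n_noncompliant = n[[4]],
               p_successful = if (n_ok) n[[1]] / n_ok else NA_real_,
               p_unsuccessful = if (n_ok) n[[2]] / n_ok else NA_real_,
               p_incomplete = if (n_ok) n[[3]] / n_ok else NA_real_)
  }))
  tpl <- do.call(rbind, lapply(c("successful", "unsuccessful"), function(o) {
    v <- df$taps_per_lap[df$outcome == o & !is.na(df$taps_per_lap)]
    data.frame(outcome = o, n = length(v),
               mean_taps_per_lap = if (length(v)) mean(v) else NA_real_,
               sd_taps_per_lap = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  list(by_tempo = by_tempo, taps_per_lap = tpl)
}
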