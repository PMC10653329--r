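test_that("tap relative phase follows the nearest-beat definition with the tie convention", {
  tr <- tap_trial("t", tempo_bpm = 120, cue_time = 7,
                  tap_times = c(0.9, 1.5, 2.1, 2.75))
  s <- tap_relative_phase(tr)
  expect_equal(s$psi_wrapped[1], 0.4 * pi)    # tap precedes beat: positive
  expect_equal(s$psi_wrapped[2], 0)           # tap on a beat
  expect_equal(s$psi_wrapped[3], -0.4 * pi)   # tap after beat: negative
  expect_equal(s$psi_wrapped[4], pi)          # halfway tie -> later beat, +pi
  expect_error(tap_relative_phase(
    tap_trial("e", 120, 7, numeric(0))), "no taps")
})

test_that("unwrapping corrects jumps beyond pi and round-trips with wrapping", {
  s <- unwrap_series(make_series(c(0.1, 0.3, 0.5)))
  expect_equal(s$psi_unwrapped, c(0.1, 0.3, 0.5))
  s <- unwrap_series(make_series(c(3.0, -3.0)))
  expect_equal(s$psi_unwrapped, c(3.0, 3.0 + (2 * pi - 6.0)), tolerance = 1e-6)
  # property: wrap(unwrap(x)) == x, and offsets are whole cycles
  set.seed(42)
  for (i in 1:20) {
    x <- runif(50, -pi, pi)
    u <- unwrap_series(make_series(x))$psi_unwrapped
    rewrapped <- u - 2 * pi * round((u - x) / (2 * pi))
    expect_equal(rewrapped, x)
  }
})

test_that("initial in-phase range uses the second half of the pre-cue interval", {
  # pre-cue psi: first half 0.3, second half the documented triple
  psi <- c(rep(0.3, 7), 0.05, 0.12, -0.02, rep(0.1, 3))
  tr <- trial_from_psi(c(psi, rep(0.1, 5)), tempo_bpm = 120, cue_time = 6.5)
  s <- tap_relative_phase(tr)
  # constrain to the exact taps: second half of [first tap, 6.5] is [3.5, 6.5]
  r <- initial_inphase_range(tr, s)
  expect_equal(r$lo, -0.02)
  expect_equal(r$hi, 0.12)
  expect_equal(r$width, 0.14)
  # constant pre-cue phase: zero-width range
  tr2 <- trial_from_psi(rep(0.1, 20), cue_time = 7)
  r2 <- initial_inphase_range(tr2)
  expect_equal(r2$width, 0)
  # too few taps in the half-interval -> undeterminable
  tr3 <- tap_trial("few", 120, cue_time = 7, tap_times = c(0.5, 1.0, 6.9))
  expect_null(initial_inphase_range(tr3))
  # drifting pre-cue phase beyond the width bound -> undeterminable
  tr4 <- trial_from_psi(seq(0, 4, length.out = 14), cue_time = 7)
  expect_null(initial_inphase_range(tr4))
})

test_that("lap counting floors the phase excursion in whole cycles from the range minimum", {
  r <- list(lo = 0.1, hi = 0.2, width = 0.1)
  lap_series <- function(top) make_series(c(0.1, r$lo + top), unwrapped = TRUE)
  expect_identical(count_laps(lap_series(6.5), r), 1L)
  expect_identical(count_laps(lap_series(0.4), r), 0L)
  expect_identical(count_laps(lap_series(27), r), 4L)
  # exact whole cycles are not floored down by representation error
  expect_identical(count_laps(lap_series(2 * pi), r), 1L)
})

test_that("the phasing window brackets the ramp and counts its taps", {
  K <- 15L
  tr <- trial_from_psi(ramp_psi(laps = 1, k_ramp = K), cue_time = 7)
  s <- unwrap_series(tap_relative_phase(tr))
  r <- initial_inphase_range(tr, s)
  laps <- count_laps(s, r)
  expect_identical(laps, 1L)
  w <- phasing_window(s, r, laps)
  expect_identical(w$taps_in_window, K)
  # a trial that never leaves the range has an empty window
  tr0 <- trial_from_psi(rep(0.2, 25), cue_time = 7)
  s0 <- unwrap_series(tap_relative_phase(tr0))
  r0 <- initial_inphase_range(tr0, s0)
  w0 <- phasing_window(s0, r0, count_laps(s0, r0))
  expect_identical(w0$taps_in_window, 0L)
})

test_that("full classification labels ramp fixtures and flags undeterminable trials", {
  o1 <- classify_trial(trial_from_psi(ramp_psi(laps = 1)))
  expect_identical(o1$outcome, "successful")
  expect_identical(o1$laps, 1L)
  expect_equal(o1$taps_per_lap, 15)
  o4 <- classify_trial(trial_from_psi(ramp_psi(laps = 4, k_ramp = 24)))
  expect_identical(o4$outcome, "unsuccessful")
  expect_identical(o4$laps, 4L)
  expect_equal(o4$taps_per_lap, 6)
  # drifting before the cue: noncompliant, nothing else defined
  on <- classify_trial(trial_from_psi(seq(0, 12, length.out = 30)))
  expect_identical(on$outcome, "noncompliant")
  expect_true(is.na(on$laps))
  expect_true(is.na(on$taps_per_lap))
})

test_that("incomplete subtypes follow the extended-band criteria with their precedence", {
  a <- 0.2
  jig <- c(-0.05, 0.05)            # gives the initial range a nonzero width
  pre <- a + rep(jig, 7)
  mk <- function(post) trial_from_psi(c(pre, post), cue_time = 7)
  # trapped: stays within range +/- one width
  o <- classify_trial(mk(a + rep(c(-0.12, 0.12), 10)))
  expect_identical(o$outcome, "incomplete")
  expect_identical(o$subtype, "trapped")
  # return: rises toward pi, falls back into the band
  o <- classify_trial(mk(a + c(pi * sin(pi * (1:16) / 17), rep(0, 4))))
  expect_identical(o$subtype, "return")
  # halfway: rises and holds outside the band
  o <- classify_trial(mk(a + c(seq(0.3, 2.4, length.out = 10), rep(2.4, 6))))
  expect_identical(o$subtype, "halfway")
  # backward: leaves the band downward only
  o <- classify_trial(mk(a - c(seq(0.3, 2.4, length.out = 10), rep(2.4, 6))))
  expect_identical(o$subtype, "backward")
})

test_that("classification is invariant to a common time shift", {
  for (tmpl in all_templates(jitter_sd = 0.01)) {
    g <- generate_trial(tmpl, make_stimulus(100), seed = 7)
    tr <- g$trial
    sh <- tap_trial(tr$trial_id, tr$tempo_bpm,
                    cue_time = tr$cue_time + 13.7,
                    tap_times = tr$tap_times + 13.7,
                    first_beat_time = tr$first_beat_time + 13.7)
    o1 <- classify_trial(tr)
    o2 <- classify_trial(sh)
    expect_identical(o1$outcome, o2$outcome)
    expect_identical(o1$subtype, o2$subtype)
    expect_identical(o1$laps, o2$laps)
    expect_equal(o1$taps_in_window, o2$taps_in_window)
  }
})

test_that("dataset summaries tabulate outcomes and gradualness by class", {
  outcomes <- list(
    new_outcome("a", 100, 1L, "successful", 20),
    new_outcome("b", 100, 1L, "successful", 22),
    new_outcome("c", 100, 1L, "successful", 21),
    new_outcome("d", 100, 3L, "unsuccessful", 8)
  )
  s <- summarize_dataset(outcomes)
  row <- s$by_tempo[s$by_tempo$tempo_bpm == 100, ]
  expect_equal(row$p_successful, 0.75)
  expect_equal(row$p_unsuccessful, 0.25)
  expect_equal(row$p_incomplete, 0)
  tpl <- s$taps_per_lap
  expect_equal(tpl$mean_taps_per_lap[tpl$outcome == "successful"], 21)
  expect_equal(tpl$mean_taps_per_lap[tpl$outcome == "unsuccessful"], 8)
})
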