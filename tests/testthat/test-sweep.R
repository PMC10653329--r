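# A tiny hand-built sweep object for arithmetic tests.
toy_sweep <- function(outcome, tpl = NULL) {
  if (is.null(tpl)) tpl <- matrix(NA_real_, nrow(outcome), ncol(outcome))
  structure(list(delta_values = seq_len(nrow(outcome)),
                 gamma_values = seq_len(ncol(outcome)),
                 tempo_bpm = 120, rho = 0.7, laps = NULL,
                 taps_per_lap = tpl, outcome = outcome),
            class = "phasing_sweep")
}

test_that("a toy grid around the three regimes lands each in its expected cell", {
  sw <- run_sweep(c(0.5, 1, 3), c(5, 15, 25), model_stimulus(120))
  expect_identical(sw$outcome[1, 2], "incomplete")     # Delta 0.5, gamma 15
  expect_identical(sw$outcome[2, 2], "successful")     # Delta 1, gamma 15
  expect_identical(sw$outcome[3, 2], "unsuccessful")   # Delta 3, gamma 15
  # weak intention with strong adaptation cannot escape; the reverse overshoots
  expect_identical(sw$outcome[1, 3], "incomplete")
  expect_identical(sw$outcome[3, 1], "unsuccessful")
  # every cell carries exactly one label and the maps share the grid shape
  expect_false(anyNA(sw$outcome))
  expect_true(all(sw$outcome %in% c("successful", "unsuccessful", "incomplete")))
  expect_identical(dim(sw$laps), dim(sw$outcome))
  expect_identical(dim(sw$taps_per_lap), dim(sw$outcome))
})

test_that("sweeps are deterministic", {
  a <- run_sweep(c(0.5, 3), c(10, 20), model_stimulus(100))
  b <- run_sweep(c(0.5, 3), c(10, 20), model_stimulus(100))
  expect_identical(a$laps, b$laps)
  expect_identical(a$taps_per_lap, b$taps_per_lap)
})

test_that("outcomes transition unsuccessful -> successful -> incomplete up each column of adaptation", {
  sw <- run_sweep(seq(0.5, 3.5, length.out = 5), seq(2, 28, length.out = 5),
                  model_stimulus(120))
  rank <- matrix(match(sw$outcome,
                       c("unsuccessful", "successful", "incomplete")),
                 nrow(sw$outcome))
  for (i in seq_len(nrow(rank))) {
    expect_true(all(diff(rank[i, ]) >= 0),
                label = sprintf("monotone staircase along gamma at Delta %g",
                                sw$delta_values[i]))
  }
})

test_that("the anti-diagonal mask keeps the balanced-parameter band", {
  d <- seq(0, 4, length.out = 5)
  g <- seq(0, 30, length.out = 5)
  m <- antidiagonal_mask(d, g, 0.5)
  expect_true(m[3, 3])              # center: x + y = 1 exactly
  expect_false(m[1, 1])             # corner: |0 + 0 - 1| = 1
  expect_true(m[1, 5] && m[5, 1])   # anti-diagonal corners
  expect_identical(dim(m), c(5L, 5L))
  # widest band covers everything
  expect_true(all(antidiagonal_mask(d, g, 1)))
  # center stays included for any positive half-width
  expect_true(antidiagonal_mask(d, g, 0.01)[3, 3])
})

test_that("outcome proportions and taps-per-lap means aggregate masked cells", {
  oc <- matrix(c("successful", "unsuccessful", "unsuccessful", "incomplete"),
               2, 2)
  tpl <- matrix(c(21, 8, 10, NA), 2, 2)
  sw <- toy_sweep(oc, tpl)
  pr <- outcome_proportions(sw)
  expect_equal(pr$fraction, c(0.25, 0.5, 0.25))
  expect_equal(sum(pr$n), 4)
  m <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  pr1 <- outcome_proportions(sw, m)
  expect_equal(pr1$fraction, c(1, 0, 0))
  tl <- sweep_taps_per_lap(sw)
  expect_equal(tl$mean_taps_per_lap[tl$outcome == "successful"], 21)
  expect_equal(tl$mean_taps_per_lap[tl$outcome == "unsuccessful"], 9)
  # absent class reported as missing
  tl1 <- sweep_taps_per_lap(toy_sweep(matrix("incomplete", 2, 2)))
  expect_true(all(is.na(tl1$mean_taps_per_lap)))
})
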