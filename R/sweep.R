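#' Sweep the intention parameters of the phasing model
#'
#' Runs [simulate_context_model()] for every combination of the target
#' phase-advance rate `Delta` and the frequency-adaptation rate `gamma`,
#' scoring each cell by lap count (successful = 1 lap, unsuccessful > 1,
#' incomplete = 0) and by taps per lap over the model's phasing window
#' ([sim_taps_per_lap()]).
#' The sweep emulates naive participants exploring different intention
#' "settings" while the involuntary phase attraction `c` stays fixed.
#'
#' Cells are independent and the integrator is deterministic, so results do
#' not depend on evaluation order; a cell whose simulation fails is marked
#' `NA` without aborting the sweep.
#'
#' @param delta_values Strictly increasing grid of `Delta` (rad/s).
#' @param gamma_values Strictly increasing grid of `gamma` (1/s).
#' @param stim A [stimulus_spec()]; [model_stimulus()] defaults match the
#'   model experiments (60 s, cue at 5 s).
#' @param base A [context_params()] supplying the fixed parameters
#'   (`c`, `lambda`, `psi_theta`); its `rho` (or the 100 ms-FWHM calibration
#'   when `NULL`) is used for the whole sweep.
#' @param dt Integration step (s).
#' @return A `phasing_sweep` object: `delta_values`, `gamma_values`,
#'   `tempo_bpm`, matrices `laps`, `taps_per_lap` and character matrix
#'   `outcome` (rows index `Delta`, columns `gamma`).
#' @examples
#' \donttest{
#' sw <- run_sweep(c(0.5, 1, 3), c(5, 15, 25), model_stimulus(120))
#' sw$outcome
#' }
#' @export
run_sweep <- function(delta_values, gamma_values, stim,
                      base = context_params(), dt = 0.001) {
  stopifnot(all(diff(delta_values) > 0), all(diff(gamma_values) > 0),
            inherits(stim, "stimulus_spec"))
  rho <- base$rho
  if (is.null(rho)) rho <- calibrate_rho(stim$omega0)
  nd <- length(delta_values)
  ng <- length(gamma_values)
  laps <- matrix(NA_integer_, nd, ng)
  tpl <- matrix(NA_real_, nd, ng)
  for (j in seq_len(ng)) {
    for (i in seq_len(nd)) {
      p <- context_params(c = base$c, gamma = gamma_values[j],
                          lambda_pre = base$lambda_pre,
                          lambda_post = base$lambda_post,
                          Delta = delta_values[i],
                          psi_theta = base$psi_theta, rho = rho)
      cell <- tryCatch({
        sim <- simulate_context_model(p, stim, dt = dt)
        laps_ij <- count_sim_laps(sim)
        list(laps = laps_ij, tpl = sim_taps_per_lap(sim, laps_ij))
      }, error = function(e) NULL)
      if (!is.null(cell)) {
        laps[i, j] <- cell$laps
        tpl[i, j] <- cell$tpl
      }
    }
  }
  outcome <- matrix(NA_character_, nd, ng)
  outcome[!is.na(laps) & laps == 1] <- "successful"
  outcome[!is.na(laps) & laps > 1] <- "unsuccessful"
  outcome[!is.na(laps) & laps == 0] <- "incomplete"
  structure(
    list(delta_values = delta_values, gamma_values = gamma_values,
         tempo_bpm = stim$tempo_bpm, rho = rho, laps = laps,
         taps_per_lap = tpl, outcome = outcome,
         base = unclass(base), dt = dt),
    class = "phasing_sweep"
  )
}

#' @export
print.phasing_sweep <- function(x, ...) {
  n <- table(factor(x$outcome, levels = OUTCOME_LEVELS[1:3]))
  cat(sprintf("<phasing_sweep: %d x %d grid at %g BPM (rho = %.4f)>\n",
              length(x$delta_values), length(x$gamma_values),
              x$tempo_bpm, x$rho))
  cat(sprintf("  successful %d, unsuccessful %d, incomplete %d, failed %d\n",
              n[[1]], n[[2]], n[[3]], sum(is.na(x$outcome))))
  invisible(x)
}

#' @export
plot.phasing_sweep <- function(x, ...) {
  code <- matrix(match(x$outcome, OUTCOME_LEVELS[1:3]),
                 nrow(x$outcome), ncol(x$outcome))
  graphics::image(x$delta_values, x$gamma_values, code,
                  col = c("#2b8cbe", "#e34a33", "#fdbb84"),
                  xlab = expression(Delta ~ "(rad/s)"),
                  ylab = expression(gamma ~ "(1/s)"), ...)
  invisible(x)
}

#' Anti-diagonal band mask over a sweep grid
#'
#' Restricts analysis to the band around the grid's anti-diagonal, where
#' the balance between the intention parameters varies while their
#' (normalized) sum stays comparable — the region naive participants
#' plausibly explore. Cell `(i, j)` is included iff
#' `|x_i + y_j - 1| <= band_halfwidth` with `x`, `y` the axis positions
#' rescaled to `[0, 1]`.
#'
#' @param delta_values,gamma_values Grid axes (as in [run_sweep()]).
#' @param band_halfwidth Half-width of the band in normalized units,
#'   in `(0, 1]` (default 0.25).
#' @return Logical matrix (`length(delta_values)` x
#'   `length(gamma_values)`).
#' @export
antidiagonal_mask <- function(delta_values, gamma_values,
                              band_halfwidth = 0.25) {
  stopifnot(band_halfwidth > 0)
  x <- (delta_values - min(delta_values)) / diff(range(delta_values))
  y <- (gamma_values - min(gamma_values)) / diff(range(gamma_values))
  abs(outer(x, y, `+`) - 1) <= band_halfwidth + 1e-12
}

#' Outcome counts and proportions within a sweep mask
#'
#' @param sweep A `phasing_sweep`.
#' @param mask Logical matrix from [antidiagonal_mask()]; default includes
#'   every cell.
#' @return Data frame with one row per outcome (`successful`,
#'   `unsuccessful`, `incomplete`): counts and fractions of the non-failed
#'   masked cells (fractions sum to 1).
#' @export
outcome_proportions <- function(sweep, mask = NULL) {
  stopifnot(inherits(sweep, "phasing_sweep"))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(sweep$outcome),
                                    ncol(sweep$outcome))
  stopifnot(identical(dim(mask), dim(sweep$outcome)))
  oc <- sweep$outcome[mask]
  oc <- oc[!is.na(oc)]
  n <- vapply(OUTCOME_LEVELS[1:3], function(o) sum(oc == o), integer(1))
  data.frame(outcome = OUTCOME_LEVELS[1:3], n = as.integer(n),
             fraction = if (length(oc)) n / length(oc) else rep(NA_real_, 3),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean taps per lap by outcome class within a sweep mask
#'
#' @inheritParams outcome_proportions
#' @return Data frame with rows `successful` and `unsuccessful`: number of
#'   masked cells in the class and their mean taps per phasing lap (`NA`
#'   when the class is absent).
#' @export
sweep_taps_per_lap <- function(sweep, mask = NULL) {
  stopifnot(inherits(sweep, "phasing_sweep"))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(sweep$outcome),
                                    ncol(sweep$outcome))
  do.call(rbind, lapply(c("successful", "unsuccessful"), function(o) {
    sel <- mask & !is.na(sweep$outcome) & sweep$outcome == o
    v <- sweep$taps_per_lap[sel]
    v <- v[!is.na(v)]
    data.frame(outcome = o, n = length(v),
               mean_taps_per_lap = if (length(v)) mean(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Tempo-effect experiment: sweeps across metronome tempi
#'
#' Repeats [run_sweep()] at each tempo with the pulse width recalibrated so
#' its temporal FWHM stays constant (100 ms by default), then tabulates
#' outcome proportions and taps-per-lap within the anti-diagonal band.
#' This is the model-side analogue of varying metronome tempo in the human
#' experiment: a fixed-duration attraction basin occupies more of a short
#' period, strengthening in-phase attraction at fast tempi.
#'
#' @param tempi Tempi in BPM (default `seq(80, 140, 10)`).
#' @param delta_values,gamma_values Grid axes (defaults: 21 points over
#'   `[0, 4]` rad/s and `[0, 30]` 1/s).
#' @param band_halfwidth Anti-diagonal band half-width (default 0.25).
#' @param base Fixed model parameters ([context_params()]).
#' @param dt Integration step (s).
#' @param stim_fun Tempo-to-stimulus mapping (default [model_stimulus()]).
#' @return List with `summary` (data frame: tempo, outcome fractions, mean
#'   taps/lap by class) and `sweeps` (the per-tempo `phasing_sweep`
#'   objects).
#' @export
tempo_sweep <- function(tempi = seq(80, 140, by = 10),
                        delta_values = seq(0, 4, length.out = 21),
                        gamma_values = seq(0, 30, length.out = 21),
                        band_halfwidth = 0.25, base = context_params(),
                        dt = 0.001, stim_fun = model_stimulus) {
  mask <- antidiagonal_mask(delta_values, gamma_values, band_halfwidth)
  sweeps <- lapply(tempi, function(tp) {
    run_sweep(delta_values, gamma_values, stim_fun(tp), base = base, dt = dt)
  })
  summary <- do.call(rbind, Map(function(tp, sw) {
    pr <- outcome_proportions(sw, mask)
    tpl <- sweep_taps_per_lap(sw, mask)
    data.frame(tempo_bpm = tp,
               f_successful = pr$fraction[pr$outcome == "successful"],
               f_unsuccessful = pr$fraction[pr$outcome == "unsuccessful"],
               f_incomplete = pr$fraction[pr$outcome == "incomplete"],
               tpl_successful =
                 tpl$mean_taps_per_lap[tpl$outcome == "successful"],
               tpl_unsuccessful =
                 tpl$mean_taps_per_lap[tpl$outcome == "unsuccessful"])
  }, tempi, sweeps))
  list(summary = summary, sweeps = sweeps, mask = mask)
}
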