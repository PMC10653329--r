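#' Analytic pulse kernel
#'
#' The complex pulse kernel \eqn{h(x, \rho) = (1-\rho) e^{ix} / (1 - \rho
#' e^{ix})}, a 2\eqn{\pi}-periodic analytic function whose amplitude is a
#' Poisson-kernel-shaped pulse concentrated at \eqn{x = 0} with unit peak.
#' The width parameter \eqn{\rho \in [0, 1)} sharpens the pulse as it grows;
#' at \eqn{\rho = 0} the amplitude is flat (\eqn{h = e^{ix}}) and the derived
#' coupling reduces to sine coupling.
#'
#' @param x Phase angle in radians (vectorized).
#' @param rho Pulse-width parameter, in `[0, 1)`.
#' @return Complex vector of kernel values.
#' @examples
#' Mod(pulse_h(0, 0.5))            # 1: unit peak
#' Mod(pulse_h(pi, 0.5))           # (1 - 0.5)/(1 + 0.5) = 1/3
#' @export
pulse_h <- function(x, rho) {
  check_rho(rho)
  eix <- exp(1i * x)
  (1 - rho) * eix / (1 - rho * eix)
}

#' Pulse-like coupling function
#'
#' Coupling between an oscillator at phase `phi` and a stimulus at phase
#' `theta`: \eqn{f(\phi, \theta, \rho) = \mathrm{Im}[h(\theta, \rho) \,
#' h(-\phi, \rho)]}. The product of two pulse kernels makes the interaction
#' strong only when both the tap and the metronome tick are near phase zero,
#' i.e. close in time. At \eqn{\rho = 0} this is exactly
#' \eqn{\sin(\theta - \phi)}.
#'
#' @param phi Oscillator phase (rad).
#' @param theta Stimulus phase (rad).
#' @inheritParams pulse_h
#' @return Numeric coupling value(s).
#' @export
coupling_f <- function(phi, theta, rho) {
  Im(pulse_h(theta, rho) * pulse_h(-phi, rho))
}

#' Context-dependent gating function
#'
#' Gates the intentional frequency bias. While the unwrapped relative phase
#' `psi` is at or below the threshold `psi_theta` the gate is fully open
#' (returns 1), so the bias can drive the escape from the in-phase attractor.
#' Beyond the threshold the gate closes when tap and tick approach each other
#' in time: \eqn{g = 1 - |h(\theta, \rho) h(-\phi, \rho)|}, which lies in
#' `[0, 1]` because the kernel has unit peak. Weak bias near re-alignment
#' lets frequency adaptation take over and end the phasing lap.
#'
#' @inheritParams coupling_f
#' @param psi Unwrapped relative phase (rad). Recycled against `phi`/`theta`.
#' @param psi_theta Switching threshold (rad), default `pi/2`.
#' @return Numeric gate value(s) in `[0, 1]`.
#' @export
gating_g <- function(phi, theta, psi, rho, psi_theta = pi / 2) {
  amp <- Mod(pulse_h(theta, rho) * pulse_h(-phi, rho))
  ifelse(psi <= psi_theta, 1, 1 - amp)
}

#' Temporal full width at half maximum of the pulse
#'
#' Width, in seconds, of the pulse amplitude \eqn{t \mapsto |h(\omega_0 t,
#' \rho)|} around \eqn{t = 0}, at half its (unit) peak. Holding this width
#' constant across metronome tempi models a temporal basin of in-phase
#' attraction of fixed duration: the same window in milliseconds occupies a
#' larger fraction of a short period, so attraction is effectively stronger
#' at fast tempi.
#'
#' The half-max crossing is located by bracketed root-finding on
#' \eqn{(0, \pi)}. For \eqn{\rho \le 1/3} the amplitude never falls to half
#' its peak (its minimum is \eqn{(1-\rho)/(1+\rho) \ge 1/2}), so the width is
#' undefined and an error is raised.
#'
#' @param rho Pulse-width parameter in `(1/3, 1)`.
#' @param omega0 Stimulus angular frequency (rad/s), `> 0`.
#' @return FWHM in seconds (scalar).
#' @examples
#' pulse_fwhm_time(0.7012, 4 * pi)  # ~0.100 s at 120 BPM
#' @export
pulse_fwhm_time <- function(rho, omega0) {
  stopifnot(length(rho) == 1, length(omega0) == 1)
  if (!is.finite(omega0) || omega0 <= 0) stop("omega0 must be positive")
  check_rho(rho)
  if (rho <= 1 / 3) {
    stop("pulse too broad: half maximum is not attained for rho <= 1/3")
  }
  half <- function(x) Mod(pulse_h(x, rho)) - 0.5
  x <- stats::uniroot(half, c(1e-12, pi), tol = 1e-10)$root
  2 * x / omega0
}

#' Calibrate the pulse width to a target temporal FWHM
#'
#' Inverse of [pulse_fwhm_time()]: finds the `rho` whose pulse has the given
#' full width at half maximum (seconds) at stimulus frequency `omega0`. Uses
#' bisection over `rho`, exploiting that the width is strictly decreasing in
#' `rho`. With the default 100 ms width this reproduces the per-tempo pulse
#' widths used throughout the model experiments, e.g. `rho = 0.7870` at
#' 80 BPM and `0.6630` at 140 BPM.
#'
#' @param omega0 Stimulus angular frequency (rad/s).
#' @param target_width Target FWHM in seconds (default 0.1 = 100 ms). Must be
#'   smaller than the stimulus period.
#' @param tol Absolute tolerance on the achieved width, seconds.
#' @return Calibrated `rho` (scalar in `(1/3, 1)`).
#' @examples
#' round(calibrate_rho(2 * pi * 80 / 60), 4)   # 0.7870
#' @export
calibrate_rho <- function(omega0, target_width = 0.1, tol = 1e-6) {
  stopifnot(length(omega0) == 1, omega0 > 0, target_width > 0, tol > 0)
  period <- 2 * pi / omega0
  if (target_width >= period) {
    stop("target_width must be smaller than the stimulus period (",
         signif(period, 6), " s)")
  }
  lo <- 1 / 3 + 1e-9
  hi <- 1 - 1e-9
  # fwhm is strictly decreasing in rho: fwhm(lo) ~ period, fwhm(hi) ~ 0
  f_lo <- pulse_fwhm_time(lo, omega0) - target_width
  f_hi <- pulse_fwhm_time(hi, omega0) - target_width
  if (f_lo < 0 || f_hi > 0) stop("no rho in (1/3, 1) attains the target width")
  while (TRUE) {
    mid <- (lo + hi) / 2
    fm <- pulse_fwhm_time(mid, omega0) - target_width
    if (abs(fm) < tol || (hi - lo) < 1e-14) return(mid)
    if (fm > 0) lo <- mid else hi <- mid
  }
}

#' Pulse width for a metronome tempo
#'
#' Convenience wrapper: `rho` calibrated so the pulse FWHM equals
#' `width` seconds at the given tempo in beats per minute.
#'
#' @param tempo_bpm Metronome tempo, beats/min.
#' @param width Target FWHM (s), default 0.1.
#' @return Calibrated `rho` (vectorized over `tempo_bpm`).
#' @export
rho_for_tempo <- function(tempo_bpm, width = 0.1) {
  vapply(tempo_bpm, function(b) calibrate_rho(bpm_to_omega(b), width),
         numeric(1))
}

check_rho <- function(rho) {
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(rho < 0) || any(rho >= 1)) {
    stop("rho must lie in [0, 1)")
  }
  invisible(rho)
}
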