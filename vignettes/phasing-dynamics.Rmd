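---
title: "Modeling and scoring phasing performance against a metronome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and scoring phasing performance against a metronome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasing)
```

## The task and the dynamics

Phasing is a musical technique in which a performer deliberately drifts out
of phase with a steady rhythm and realigns exactly one cycle later. Against
a metronome, the tapper must first hold in-phase tapping, then — on a cue —
advance each tap slightly ahead of the beat until the accumulated relative
phase has grown by $2\pi$, and then stop advancing. The task pits two
forces against each other: the involuntary attraction toward in-phase
synchronization, and the intention to desynchronize at a controlled rate.

The package treats the tapper as a forced phase oscillator. The simplest
version has a fixed natural frequency $\omega$ and sine coupling:

$$\frac{d\phi}{dt} = \omega + c\,\sin(\theta - \phi), \qquad
\theta = \omega_0 t,$$

whose relative phase $\psi = \phi - \theta$ obeys the Adler flow
$\dot\psi = \Delta\omega - c \sin\psi$ with detuning
$\Delta\omega = \omega - \omega_0$. This model locks for
$|\Delta\omega| \le c$ (at $\psi^* = \arcsin(\Delta\omega/c)$) and drifts
indefinitely otherwise — it can reproduce a tapper who fails to escape
in-phase tapping or one who phases forever, but never a tapper who stops
after exactly one lap (`fixed_points()`, `simulate_fixed_detuning()`).

The full model therefore makes the natural frequency a state variable and
the intention context-dependent:

$$\frac{d\phi}{dt} = \omega + c\,f(\phi,\theta,\rho), \qquad
\frac{d\omega}{dt} = \gamma f(\phi,\theta,\rho)
  - \lambda\, g(\phi,\theta,\rho)\,(\dot\psi - \Delta).$$

Three ingredients matter:

* **Pulse coupling.** Metronome ticks and taps are discrete events, so the
  coupling acts only when tap and tick are close in time. The kernel is
  the unit-peak analytic pulse
  $h(x,\rho) = (1-\rho)e^{ix}/(1-\rho e^{ix})$, and
  $f = \mathrm{Im}[h(\theta,\rho)h(-\phi,\rho)]$. At $\rho = 0$ this is
  exactly $\sin(\theta-\phi)$, so the sine model is the flat-pulse limit.
* **Frequency adaptation** ($\gamma$) pulls $\omega$ toward $\omega_0$,
  the synchronizing force.
* **Gated intentional bias** ($\lambda$, $\Delta$). The tapper tries to
  advance the relative phase at target rate $\Delta$ (rad/s); the bias term
  pushes $\omega$ up whenever $\dot\psi < \Delta$. The gate $g$ is fully
  open ($g = 1$) while unwrapped $\psi$ is below the threshold
  $\psi_\theta$, easing the escape; beyond it,
  $g = 1 - |h(\theta,\rho)h(-\phi,\rho)|$ closes the gate as tap and tick
  realign, letting adaptation land the oscillator back in phase — or
  failing to, if the bias is too strong.

The right-hand side of the frequency equation contains $\dot\psi$; the
package substitutes the exact identity
$\dot\psi = \omega + c f - \omega_0$ from the phase equation, giving an
explicit first-order system in $(\phi, \omega)$.

## Parameters, defaults, units

| symbol | argument | default | units | role |
|---|---|---|---|---|
| $c$ | `c` | 30 | 1/s | phase attraction (involuntary) |
| $\gamma$ | `gamma` | 15 | 1/s | frequency adaptation rate |
| $\lambda$ | `lambda_pre`, `lambda_post` | 0, 3 | — | bias strength before/after cue |
| $\Delta$ | `Delta` | 1 | rad/s | target phase-advance rate (gradualness) |
| $\psi_\theta$ | `psi_theta` | $\pi/2$ | rad | gate-switch threshold |
| $\rho$ | `rho` | calibrated | — | pulse width parameter |

The defaults are the replication values used for every model experiment in
the package. With them, the target rate alone separates the three behavior
regimes at 120 BPM: $\Delta = 1$ gives exactly one phasing lap
(successful), $\Delta = 3$ overshoots and keeps phasing (unsuccessful),
and $\Delta = 0.5$ cannot escape the in-phase attractor (incomplete):

```{r regimes}
stim <- model_stimulus(120)   # 60 s, intention switch at 5 s
sapply(c(0.5, 1, 3), function(D)
  count_sim_laps(simulate_context_model(context_params(Delta = D), stim)))
```

### Why $\rho$ is calibrated per tempo

Distractor experiments in sensorimotor synchronization suggest the
temporal basin of in-phase attraction has a roughly constant width in
*absolute time*, not in phase. The package therefore chooses $\rho$ per
tempo so that the full width at half maximum of $|h(\omega_0 t, \rho)|$ is
100 ms regardless of tempo (`calibrate_rho()`). A fixed 100 ms basin
occupies a larger fraction of a short period, so in-phase attraction is
effectively stronger at fast tempi — this single assumption carries the
model's tempo effect.

```{r rho}
data.frame(bpm = seq(80, 140, 10),
           rho = round(rho_for_tempo(seq(80, 140, 10)), 4))
```

For this kernel the amplitude minimum is $(1-\rho)/(1+\rho)$, so a half
maximum only exists for $\rho > 1/3$; `pulse_fwhm_time()` raises a domain
error below that. Calibration is a bisection on $\rho$ (the width is
strictly decreasing in $\rho$), with a tolerance of $10^{-6}$ s.

## Scoring tapping trials

The analysis pipeline mirrors the experimental procedure and is the same
for human and simulated taps:

1. **Relative phase** of each tap against the *nearest* beat,
   $\psi_n = 2\pi(m_n - t_n)/T \in (-\pi, \pi]$, positive when the tap
   leads the beat. A tap exactly halfway between beats is assigned to the
   later beat ($+\pi$), a deterministic convention consistent with the
   sign rule.
2. **Unwrapping** (MATLAB-convention, via the signal package) so the phase
   can climb continuously past $\pi$.
3. **Initial in-phase range**: min and max wrapped $\psi$ over the second
   half of the pre-cue interval (taken per trial, since mean tap
   asynchrony varies across people and tempi). The pre-cue interval is
   defined from the first tap to the cue. If fewer than 3 taps fall in
   that half, or the range is wider than $\pi/2$, in-phase tapping was
   never established and the trial is *noncompliant*; both thresholds are
   arguments of `classify_trial()`.
4. **Laps**: $\lfloor (\max\psi_{\text{unwrapped}} - \text{range lo}) /
   2\pi \rfloor$, floored at zero. A $10^{-9}$ additive guard keeps exact
   whole-lap trajectories (which noise-free synthetic trials produce) from
   being floored down by representation error.
5. **Phasing window**: opens after the last tap inside the initial range
   (before the first upward departure) and closes at the first tap inside
   the final range — the initial range translated up by $2\pi \cdot$ laps,
   because phasing lands on the same attractor one lap up. Taps strictly
   inside, divided by laps, give **taps per lap**, the gradualness
   statistic.
6. **Outcome**: successful (1 lap), unsuccessful (> 1), incomplete (0).
   Incomplete trials get a subtype from the initial range widened by one
   range width on each side: *trapped* (never leaves the extended band),
   *backward* (leaves downward only), *return* (leaves upward, final tap
   back inside), *halfway* (leaves upward, ends outside). The precedence
   trapped → backward → return → halfway resolves overlaps
   deterministically.

For *model* runs the pipeline needs one adjustment: a deterministic
simulation holds $\psi$ exactly constant before the cue, so the empirical
range — whose width comes from motor noise — degenerates to a point, and
the final lock (which sits slightly above $2\pi$, because a residual
gated bias balances a small negative coupling) never enters a zero-width
final range. `sim_taps_per_lap()` therefore bounds the window by the lock
values themselves: last tap still at the pre-cue phase, first tap a full
$2\pi\cdot$ laps above it. Lap counting needs no such adjustment and is
verified to agree between `count_sim_laps()` and `classify_trial()` run on
the simulated taps.

## The synthetic-trial generator

`generate_trial()` builds trials with known ground truth by inverting the
relative-phase definition tap by tap: a target unwrapped trajectory
(pre-cue plateau at the template asynchrony; then a smoothstep ramp
through the target laps, or the subtype-specific excursion — bounded
plateau, rise-and-fall, rise-and-hold, or monotone descent) is converted
to tap times via $t_n = m_n - \psi_n T/2\pi$, then Gaussian tap-time
jitter (SD a fraction of the period, truncated at $\pm 3$ SD so taps never
reorder) is added. Because placement inverts exactly the formula the
analyzer applies, the pipeline recovers every generating label perfectly
at zero jitter — the generator is an oracle for the analyzer.

The defaults emulate the experiment's structure: 2-minute stimuli at
80–140 BPM in 10-BPM steps, a cue coinciding with a beat near 7 s, three
trials per tempo, a mean pre-cue asynchrony of 0.2 rad (taps slightly
ahead of the beat, the typical direction), 20 phasing taps, and 2 % of a
period of tap jitter. What the generator does *not* emulate: drift in
asynchrony over a trial, tempo-dependent noise, serially correlated motor
noise, or hesitations mid-lap. Passing recovery tests therefore shows the
pipeline is correct on clean realizations of each outcome; it does not
certify behavior on every idiosyncrasy of real tapping.

## Parameter sweeps and the tempo effect

`run_sweep()` scores the model over a $(\Delta, \gamma)$ grid — the two
quantities a naive tapper plausibly explores while phase attraction $c$
stays fixed — and `tempo_sweep()` repeats this per tempo with $\rho$
recalibrated. Outcomes form three bands: incomplete where adaptation
dominates (upper left), unsuccessful where bias dominates (lower right),
successful in between. Analyses restrict to the anti-diagonal band
(`antidiagonal_mask()`, half-width 0.25 in normalized units), where the
balance of the two parameters varies while their sum stays comparable.

Default grid ranges are $\Delta \in [0, 4]$ rad/s and
$\gamma \in [0, 30]$ 1/s, spanning the working values above; the default
resolution for desk-scale runs is $21 \times 21$ per tempo (about 20 s
per tempo on one CPU at the 1 ms step), with denser grids available
through the same interface. Two granularity effects at desk scale are
worth knowing. First, outcome fractions move in single-cell quanta, so a
monotone trend across tempi can show one-cell reversals at $21 \times 21$
that vanish at $41 \times 41$. Second, the mean taps-per-lap over
*successful* cells mixes two opposing effects: each individual cell
phases more gradually at faster tempi, but the successful region also
grows toward high-$\Delta$ (less gradual) cells, so the band mean need
not rise with tempo even though every matched cell does.

## Numerical choices

* **Integrator**: fixed-step classical Runge–Kutta, default
  `dt = 0.001` s. The bias switch at the cue is a discontinuity; the
  switch time is required to lie on the step grid and coefficients are
  held constant over each step, so the scheme keeps full order on both
  sides and runs are bit-for-bit reproducible. Halving the step changes
  the final relative phase by far less than $10^{-4}$ rad in all regimes.
* **Events**: taps are upward crossings of the wrapped oscillator phase
  through zero (ticks likewise for the stimulus), located by linear
  interpolation between bracketing samples; `dt` must resolve at least
  200 steps per period.
* **Initial conditions**: $\phi(0) = 0$, $\omega(0) = \omega_0$ — an
  in-phase start aligned with a tick.
* **Degenerate inputs**: $\rho$ outside $[0,1)$, widths without a
  half-maximum ($\rho \le 1/3$), targets wider than a period, coarse
  steps, non-monotone tap times, and infeasible templates (per-tap phase
  increments reaching $\pi$, or taps past the stimulus end) all raise
  immediate errors rather than propagating.

## Limitations

* The model has no antiphase attractor, so it cannot produce the
  *halfway* subtype, and no stochastic term, so it cannot produce
  *backward* trials; both subtypes exist only in the synthetic generator
  and in human data.
* After a successful lap the natural frequency settles slightly above the
  stimulus frequency (a residual gated bias balanced by negative
  coupling) rather than exactly on it; lap counting is unaffected.
* The published trial counts for the deposited human dataset can only be
  recomputed with that dataset present (see the tap-table schema in
  `read_taps_csv()`; any export with per-tap timestamps, tempo, cue, and
  beat origin per trial can be converted to it).
* Simulation horizons are finite (60 s by default for model runs): cells
  whose escape would complete a lap later than the horizon are scored
  incomplete, which is part of the operational definition of the regime
  maps.
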