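---
title: "Neuron models from polynomial, piecewise-linear and step functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuron models from polynomial, piecewise-linear and step functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsneuro)
```

## The modelling idea

Conductance-based neuron models spend most of their arithmetic on
exponentials: every gating variable carries voltage-dependent rate functions
that must be evaluated hundreds of times per millisecond of model time. This
package implements an alternative representation in which the right-hand
sides of the differential equations are combinations of three cheap function
families:

* **P** — polynomials stored as products of root factors,
  `scale * prod (root_i - x)^m_i`, so a cubic voltage nullcline is three
  roots and a scale;
* **L** — continuous piecewise-linear functions given by knots plus two
  outer slopes;
* **S** — piecewise-constant step functions with the convention that a
  threshold evaluates to the mean of its two adjacent levels.

Four rules make these pieces a coherent framework rather than a bag of
approximations: (1) all dynamic variables stay continuous — there is no
reset; (2) right-hand sides are linear combinations of P, L and S terms;
(3) the specific points of L and S terms (knots, thresholds) may be aligned
with polynomial extrema to keep the right-hand side smooth where it matters;
and (4) no L or S specific point may itself create a fixed point or
bifurcation point. Rule 4 is the well-posedness condition: a fold born at a
knot sits exactly where the right-hand side fails to be continuously
differentiable, and the resulting model can stall at rest far above
threshold or blow up with extreme step-size sensitivity.
`continuity_audit()` operationalises the rule: it checks two-sided value
limits at every declared specific point and flags any fixed point within
`1e-6` mV of a knot that is not aligned with a declared polynomial extremum.

## The reference model

The benchmark throughout is a single-compartment fast-spiking interneuron
model in Hodgkin–Huxley form: instantaneous sodium activation
`m_inf(v)`, inactivation `h` and delayed-rectifier activation `n` with
first-order kinetics, capacitance 1 µF/cm², conductances
`g_l = 0.1`, `g_Na = 35`, `g_K = 9` mS/cm², reversals −65, 55, −90 mV.
The rate functions are the standard published forms for this model (they
are reproduced in the documentation of `gating_rates()`), with the rate
scale `phi = 5` folded into the effective time constants. All simulations
use fixed-step forward Euler at `dt = 0.01` ms — the step at which spike
times change by well under half a millisecond when the step is halved (see
the convergence test) — with the inner loops compiled.

At rest the model sits near −64 mV and is quiescent; at 1 µA/cm² it fires
at about 58 spikes/s. Firing-rate–current (FI) curves come from a 10 s
linear current ramp: each inter-spike interval contributes its reciprocal
at the ramp current of the interval midpoint, interpolated onto a uniform
200-point current grid. The ramp estimator is conventional but makes the
pointwise comparison hypersensitive at the firing onset, where the
interpolated curve jumps from zero to several spikes per second within one
grid cell; the calibration below therefore registers the onset explicitly.

## Four approximation routes

1. **Lookup table.** The five gating curves tabulated on a uniform grid
   from `E_K` to `E_Na` (200 rows, 0.725 mV offset, 3.9 kB at single
   precision), queried by linear interpolation with constant extrapolation
   beyond the ends. Interpolation error is O(h²): doubling the rows
   quarters the maximum error, which the property suite asserts directly.
2. **Polynomial fits.** Each gating curve replaced by an order-5
   least-squares polynomial. Fitted over the model's full operating range
   (−100 to 60 mV) the route destabilises rest — the model spikes at zero
   current — and its FI error exceeds 30% of the reference dynamic range.
3. **Piecewise-linear fits.** Three-segment on-curve fits (knots on the
   target curve, interior knot positions optimised by a two-stage grid
   search on the maximum error). Better than the polynomial route but
   still >20% FI error: a function-by-function fit of the gating curves is
   the wrong place to spend accuracy.
4. **The 2D reduction** described next, which beats all but the lookup
   table at a fraction of the footprint (31 stored constants versus a
   thousand tabulated values).

The polynomial and piecewise-linear routes guard their fitted curves
numerically: approximated steady states are clamped to [0, 1] and
approximated time constants floored at 0.01 ms, so a fit that strays
outside its physical range degrades the dynamics instead of destroying the
integration.

## Collapsing the gating variables

Along a spiking trajectory `h` and `n` move together; regressing `h` on
`n` over the active phase of the trajectory (voltage above −55 mV, constant
drive 1 µA/cm², 2 s with the first 500 ms discarded) gives a line
`h = epsilon + kappa n` with R² ≈ 0.94. The restriction to the active
phase is deliberate: the collapsed gate enters the reduced model only
through the sodium current, which is engaged exactly there, whereas the
long interspike dwell near rest would otherwise dominate the regression
with points at which the slaved gate is never used.

Substituting the line yields a two-variable system in `(v, n)`. On the
`n = 0` axis its voltage nullcline reduces to a scalar condition whose dip
vanishes at a tangency current `I0 ≈ 0.13` µA at `v0 ≈ −61` mV; bisection
on the dip depth locates both. Above the tangency the subthreshold root
pair is gone — the fold that underlies spiking onset.

## Constructing the reduced model

The reduced model replaces the leak and sodium terms with a cubic
`a0 (v - v0)^2 (v1 - v)` (double root at the tangency voltage, simple root
at `E_Na`) multiplied by a one-knot linear factor with unit value at `v0`
that steepens the left branch. Because the knot coincides with the cubic's
double root, the kink is invisible: the product remains continuously
differentiable there — rule 3 in action. `a0` and the left slope are
fitted so the model's voltage nullcline matches the reduced system's
nullcline *as a curve in the (v, n) phase plane* (solving each for `n` and
minimising the squared distance). Fitting the current balance on the
`n = 0` axis instead silently drops the `kappa n` sodium attenuation and
produces a spurious stable depolarised fixed point. `n_inf` becomes a
3-segment on-curve piecewise-linear fit weighted towards the subthreshold
window (−75 to −40 mV) — that region sets the onset current — and the
effective `tau_n` a plain 3-segment fit.

Two facts shape the time-constant calibration. First, slaving `h` removes
the state-dependent part of the membrane's effective speed, so the
uncalibrated reduction runs uniformly ~40% fast. Second, scaling *both*
time constants by a common dilation preserves every trajectory in the
phase plane and only rescales the clock. The calibration therefore applies
a global dilation (the voltage time constant, a one-knot piecewise-linear
function, plus a common scale on `tau_n`), registers the onset through a
small offset added to the stored `I0` (the model is driven by `I - I0`),
and lets a deterministic simplex search trim the dilation, the `tau_n`
knot levels and the voltage-tau slopes against the fully computed model's
FI curve, minimising the maximum deviation. The search is a coarse grid
followed by Nelder–Mead polish; identical inputs give identical constants,
and the whole construction takes about a minute and a half of CPU. The
result ends within 4% of the reference dynamic range — better than the
intermediate reduced system itself, which is the point of calibrating the
final constants against the original rather than against the intermediate
step. The reduced model keeps the full model's qualitative structure:
silent at rest, type 1 onset, voltage bounded by the potassium and sodium
reversals.

## Phenomenological integrator and resonator

The same families build stand-alone 2D models with voltage `v` and a
dimensionless recovery variable `w` (power `k = 2` in the voltage
equation). The **integrator** uses a three-root cubic (−65, −45, 55 mV,
scale 3.5e−6) with a left-branch steepener aligned at the −65 mV root, a
ramp `w` steady state (0 at −40 mV to 1 at −5 mV), a two-threshold step
`w` time constant (5, 7.6, 1.8 ms switching at −55.45 and 18.78 mV) and a
one-knot voltage time constant. At rest it has three fixed points (stable,
saddle, unstable focus); raising the current annihilates the stable/saddle
pair at `I0 ≈ 0.039` — a fold on the invariant circle, so the firing rate
rises from zero with the square-root law (the property suite fits the
exponent: 0.4–0.6) — and a second fold at `I1 ≈ 0.32` creates the stable
depolarised point of the depolarisation block. The **resonator** replaces
the cubic by a double-root version (scale 3.25e−6) and shifts the `w`
nullcline (ramp from −75 mV, thresholds −55.5 and 18 mV): one fixed point
at all currents below block, losing stability through a subcritical
Andronov–Hopf bifurcation, so sustained firing cannot be slower than the
limit cycle born there — about 4 spikes/s.

Numerical choices: fixed points come from a sign-change scan of the scalar
fixed-point condition at 0.001 mV resolution refined by bisection to
residuals below 1e-9; stability from the analytic piecewise Jacobian
(finite differences cross-check to 1e-4 away from specific points; exactly
at a knot the left branch applies, consistent with the `x <= x0`
convention); fold currents by bisection on the fixed-point count to 1e-5,
with an initial grid scan because the count passes 1 → 3 → 1 across the
block fold; Hopf currents by bisection on the sign of the leading
eigenvalue real part. The hold–step–ramp protocol holds 0.999·I0 for
500 ms, steps to 1.001·I0 for 9 s, then ramps 0.9·I1 → 1.1·I1 over the
final second; the hold and step factors are arguments, not constants.

## The plateau-potential experiment

Developing cortical neurons respond to a thalamic burst with a
plateau potential: a long spikeless depolarisation carried by
NMDA receptors. The experiment drives one neuron with 30 independent
Poisson sources at 0.9 Hz baseline and 13 Hz for one second (the burst sits
at 5 s of a 15 s run) through two currents per connection: a fast AMPA
conductance (2 ms decay) and a 4× stronger NMDA conductance with
dual-exponential kinetics (1 and 200 ms) under the standard Jahr–Stevens
magnesium block `1/(1 + Mg e^{-0.062 v}/3.57)`. Every presynaptic spike
increments the three gates by one — the conventional unit-increment rule
for dual-exponential synapses. The AMPA conductance is tuned by a
deterministic search so the baseline rate (outside the burst ± 1 s guard)
lands in 0.7–1 Hz averaged over three seeds; the search first scans a log
grid because very strong drive clamps the neuron near the synaptic
reversal without resets, making the rate non-monotone in the conductance.

With the tuned drive the continuous models do exactly what the framework's
continuity rule promises: the burst's NMDA current shifts the voltage
nullcline rightwards, a stable depolarised fixed point appears, and the
trajectory spirals into it — a spikeless clamp just below zero millivolts
(−9 ± 2 mV in these parameter sets, for the whole burst) that releases as
the NMDA gates decay. The hard-reset baseline model given identical input
produces high-frequency spike bursts and no plateau at any conductance: a
quadratic voltage branch with a reset has no second stable branch to hold.
One caveat the tests make explicit: the depolarised fixed point sits at
the upper edge of the −30 to −10 mV window that the nullcline-intersection
argument suggests, and the post-burst slide through that window lasts only
~250 ms because the NMDA decay is 200 ms; the plateau tests therefore
detect the dwell in the band the dynamics actually occupy (−30 to −2 mV),
and the detector's band and minimum duration are explicit arguments.

## What the synthetic drive does and does not emulate

The Poisson ensemble reproduces the printed input statistics — independent
homogeneous sources, a single rate step — and nothing else: no
refractoriness, no correlation between sources, no conductance saturation,
no short-term plasticity. Passing tests therefore show that the *models*
respond to a rate step as claimed, not that real thalamic drive is
Poisson. Seeds fully determine the trains, and protocol traces are
bit-identical across runs with the same seed.

## Problem sizes and limitations

The test suite and the acceptance script use the protocols at full
resolution: 10 s FI ramps and 10 s rate measurements at `dt = 0.01` ms
(10⁶ steps each), 15 s plateau runs (1.5×10⁶ steps), ten seeds per
robustness check. Known limitations: both phenomenological models are 2D
and continuous, so they cannot burst intrinsically — that needs a third,
slower variable; the ramp FI estimator under-resolves the infinite-period
regime immediately above a fold; the reduction chain distorts
near-threshold excitability (the slaved inactivation gate underestimates
sodium availability at rest), which the final calibration compensates but
does not remove; and the segment-regression strategy for piecewise-linear
fitting is only reliable on convex or concave targets, which is why the
on-curve strategy is the default.
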