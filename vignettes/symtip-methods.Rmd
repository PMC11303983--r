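---
title: "Methods: a symmetric mutual-inhibition ecosystem and its tipping-point symmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a symmetric mutual-inhibition ecosystem and its tipping-point symmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(symtip)
```

## The model

`symtip` simulates a minimal ecosystem built around mutual inhibition:
two bacterial functional groups — cyanobacteria and sulfur-reducing
bacteria — compete for one nutrient (phosphorus) and each excretes a
substrate (oxygen, sulfide) that suppresses the growth of the other
group. Positive feedback through reciprocal suppression creates two
alternative stable states: an *oxic* state dominated by cyanobacteria
(high O, low S) and an *anoxic* state dominated by sulfur reducers (high
S, low O). The five state variables are the group densities `N_CB`,
`N_SB` (cells L⁻¹) and the concentrations `O`, `S`, `P` (μM).

Growth is Monod in phosphorus, `g(P) = g_max·P/(k_P+P)`, multiplied by a
Haldane-type inhibition factor `h_X = 1/(1+X/H_X)` that halves growth
when the inhibitor reaches its half-inhibition constant `H_X`. Each
substrate is produced proportionally to its producer's gross growth,
removed by the abiotic oxidation reaction `c·O·S` (consuming both), and
exchanged with a fixed background pool at a diffusivity `α` (h⁻¹):
`α·(X_b − X)`. Phosphorus is consumed at growth over yield and diffuses
likewise.

The default parameterization (`symmetric_parameters()`) makes the two
groups exact mirror images: shared `g_max = 0.1` h⁻¹, `k_P = 0.5` μM,
`y_P = 1.67e8` cells μM⁻¹, `m = 0.04` h⁻¹; equal half-inhibition
constants `H_S = H_O = 100` μM, production constants
`p_O = p_S = 3e-8` μM cell⁻¹ and substrate backgrounds
`O_b = S_b = 100` μM; `P_b = 10` μM, `α_P = 0.1` h⁻¹, `c = 0.1`. Two
unit conventions deserve note, both resolved by dimensional analysis of
the rate equations: the half-inhibition constants enter as `X/H` and are
therefore concentrations (μM), and the oxidation coefficient `c`
multiplies `O·S` and therefore carries μM⁻¹ h⁻¹. Under this
parameterization the equations are invariant under the mirror swap
`(N_CB, O, α_O, H_S, p_O, O_b) ↔ (N_SB, S, α_S, H_O, p_S, S_b)`; the
compiled right-hand side is written so the two halves perform identical
floating-point operations, and the test suite verifies that integrated
trajectories commute with the swap to near machine precision.

## Stable-state protocol

The environmental drivers are the two substrate diffusivities. Oxygen
diffusivity spans 10⁻² to 10⁰ h⁻¹ on a log10-equispaced grid
(`driver_sequence()`, default 101 steps) while sulfide diffusivity
traverses its own range in the opposite direction. Stable states are
found by the stepwise *temporal approach*: start from
`(N_CB, N_SB, O, S, P) = (1e5, 1e5, 20, 20, 10)`, integrate 10⁶ h of
biological time at the first driver pair, record the end state, move the
drivers one step, and continue from the previous end state
(`run_direction()`). Two independent runs, one per direction of
environmental change, trace the two hysteresis branches
(`run_hysteresis()`). Both start from the same initial state; the first
step's long equilibration establishes the attractor appropriate to each
starting extreme.

To keep either group from being driven to numerical extinction while
suppressed, 1 cell L⁻¹ is added to both groups every 1000 h. This is
implemented as a genuine discrete impulse through the integrator's event
mechanism, on a global 1000-h clock. The impulse at a step's final
boundary is applied *after* the steady-state residual is measured, so the
recorded residual describes the relaxed system rather than the impulse,
and every recorded state retains at least the immigration stock in both
groups. A continuous-rate approximation is deliberately not the default;
the impulses are cheap because each gradient step is integrated in a
single stiff-solver call with ~1000 interior events.

Numerical choices: `lsoda` via deSolve with a compiled C right-hand
side; relative tolerance 1e-8; absolute tolerances scaled per variable
(1e-3 cells L⁻¹ for the densities, whose dynamic range spans ten orders
of magnitude, 1e-9 μM for concentrations). Rates inside the RHS are
evaluated on states clamped at zero so transient sub-tolerance
undershoots cannot generate spurious growth; end states are floored at
zero, with a warning only if an excursion exceeds the tolerance scale.
The relative derivative norm `max_i |f_i|/max(|x_i|, s_i)` (s = 1 cell
for densities, 10⁻³ μM for concentrations) is recorded at every step end
and steps above the diagnostic threshold (default 1e-5 h⁻¹) are flagged
with a warning — in practice only the one or two steps adjacent to a
tipping point, where relaxation is critically slowed, are flagged.
Doubling the step duration changes recorded plateau states by less than
1e-8 relative (tested), so 10⁶ h is comfortably past equilibration. An
optional early-exit mode (off by default) ends a step once the residual
has stayed below threshold for 10 consecutive immigration intervals; it
reproduces full-step states to ~1e-6 and is intended for exploratory
scans.

## Temporal mode

`temporal_pattern()` builds a piecewise-constant schedule for time-series
views: an initial hold at the anoxic-favoring extreme followed by three
staircase ramps — to the oxic extreme, back, and out again — so the
trajectory crosses a tipping point three times (anoxic→oxic,
oxic→anoxic, anoxic→oxic; the upward shifts are carried twice by oxygen
and once by sulfide). Defaults are 50 staircase steps per ramp at 10⁶ h
per step, i.e. quasi-static forcing; the recorded cadence (default
1000 h) is configurable. The transient phosphorus spike that accompanies
each regime shift — dominance changes hands faster than phosphorus is
drawn back down, so P briefly overshoots its plateau — is resolved at
this cadence to within ~2%; the spike maximum computed by the package's
own runs is ≈0.50 μM from a plateau of ≈0.334 μM, identical across the
three shifts to <0.5% (tested).

## Quantifying (a)symmetry

`detect_tipping()` measures, between each pair of consecutive stable
states, the larger of the two substrate changes, and takes the maximum
over the gradient as the tipping point; changes below a floor (0.5 log10
units per step by default) classify the response as monostable, returned
as an explicit no-tipping result. The location is the log10 midpoint of
the bracketing oxygen diffusivities — unbiased with respect to scan
direction and resolved to one step width. Ties break toward the gradient
midpoint, then the lower index, deterministically, and are flagged.

Shift magnitudes are the unsigned per-substrate changes across the
tipping step, and the *total shift magnitude* of a direction is their
sum. Two scales are provided. The default `log10` scale makes magnitudes
scale-free across the four orders of magnitude the substrates span. The
`raw` (μM) scale is the one on which the directional claims about the
scans below hold; because the mirror symmetry maps the two directions'
jumps onto each other exactly, the symmetric configuration has equal
totals on *either* scale (this equality, not the scale, is the symmetry
diagnostic). `analyze_hysteresis()` assembles a report: both tipping
points, the signed difference of total magnitudes (oxic→anoxic minus
anoxic→oxic), and the bistability width; `compare_to_symmetric()` adds
tipping-location displacements relative to a symmetric reference run.

Two scans vary one knob each while holding everything else symmetric:

* `scan_system_asymmetry()` varies the sulfur reducers' oxygen
  half-inhibition constant `H_O` (default 30–170 μM in steps of 10;
  cyanobacteria stay at 100 μM). Lower `H_O` (less oxygen-tolerant
  sulfur reducers) moves both tipping points to lower oxygen
  diffusivities and makes the oxic→anoxic total smaller than the
  anoxic→oxic total; higher `H_O` does the opposite. Both locations move
  the *same* way, leaving the bistability width essentially unchanged.
* `scan_environmental_asymmetry()` varies the sulfide-range factor
  (0–2). Factors below 1 (less sulfide variation) push the two tipping
  points *apart* (wider bistability) and inflate the oxic→anoxic total
  on the raw scale; factors above 1 pull them together and deflate it.
  At factor 0 (`α_S` frozen at 10⁻¹ h⁻¹) the oxic→anoxic tipping point
  is displaced about three times further from its symmetric location
  than the anoxic→oxic one.

In all cases the magnitude asymmetry grows monotonically with the
distance from the symmetric configuration (tested on the sub-grids
`H_O ∈ {60, 100, 140}` and factor ∈ {0.6, 1.0, 1.4}).

## Design decisions and problem sizes

* **Gradient resolution.** Tipping locations are quantized to one grid
  step, so location-displacement comparisons are resolution-limited: at
  41 steps (0.05 decades) the factor-0 displacement ratio cannot be
  resolved better than whole steps. The package default and the problem
  size used by the acceptance analysis and tests is 101 steps (0.02
  decades), where a two-direction experiment costs ~25 s; the
  displacement ratio stabilizes near 3 (2.75 at 101 steps, 3.1 in a
  0.01-decade fold search).
* **Default magnitude scale.** Detection uses log10 changes (scale-free
  and robust to the subordinate substrate's small values); directional
  sign claims about the scans are made, and tested, on the raw μM scale
  where they hold. Both are exposed via `metric =`.
* **Which post-shift value characterizes a branch.** The concentration
  "attained after an upward shift" is read as the post-shift branch
  plateau (`post_shift_plateau()`: the substrate maximum beyond the
  tipping step), not the single state immediately after the jump — the
  branch continues to rise for a few steps before leveling off, and the
  plateau is the quantity a hysteresis diagram displays. Under full
  symmetry it is ≈105.9 μM for both substrates; under factor 0.6 the two
  directions split to ≈102.5 (oxygen, oxic state) and ≈110.9 μM
  (sulfide, anoxic state).
* **Anoxic-plateau phosphorus.** At a plateau the dominant group's
  balance pins `g(P)·h = m`, so
  `P* = k_P / (g_max·h/m − 1)`; with the inhibitor of the dominant group
  nearly absent (`h → 1`) this gives `P* = 0.5/1.5 ≈ 0.334` μM, which is
  what the simulations record on the anoxic plateau. P rises along the
  branch toward ≈0.40 μM at the fold as the inhibitor leaks in.
* **Immigration as impulses.** Exact protocol fidelity first; the
  event-based impulses cost little with the compiled RHS. The recorded
  subordinate density equals the immigration stock (the relaxed remnant
  of earlier impulses is below the density tolerance), which also keeps
  log-scale plots finite.

## What the model does and does not emulate

The generator *is* the study system: there are no external data, and
every quantity the package reports is computed from the equations above
under the stated protocol. The model trades realism for symmetry — one
functional group of the ancestral three-group oxic/anoxic model is
removed, sulfate is not tracked, both groups share the sulfur reducers'
literature trait values, and the abiotic constants (backgrounds,
oxidation rate) are tuning parameters chosen to place the hysteresis
loop inside the scanned driver window. Passing tests therefore
demonstrate properties of this idealized dynamical system — mirror
symmetry, hysteresis, proportionality of response asymmetry to
system/environmental asymmetry — not quantitative predictions for any
real water column.

## Known limitations

* Tipping locations are simulation-based (stepwise protocol), not
  continuation-based; they carry one-grid-step uncertainty and the
  protocol records the step at which the old branch *loses* stability,
  not the exact fold.
* The no-tipping floor (0.5 log10 units) cleanly separates regime shifts
  from drift for all configurations scanned here, but a system with
  genuinely gradual transitions would need a problem-specific floor.
* The temporal mode's spike maxima depend mildly on the recording
  cadence and ramp staircase resolution (~2% at the defaults).
* Warnings about end-of-step residuals at the steps bracketing a tipping
  point are expected (critical slowing down); they flag reduced
  precision of those two states, not a failure of the protocol.
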