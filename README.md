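# symtip

Response symmetry of ecosystem tipping points in a symmetric
mutual-inhibition microbial model.

## The scientific problem

Ecosystems with alternative stable states — here the oxic and anoxic
states of a stratified water body — degrade and recover along hysteresis
loops: the regime shift back does not retrace the regime shift out. A
natural question for restoration ecology is whether the *magnitudes* of
the two shifts are nevertheless equal (response symmetry), and what
controls departures from equality. `symtip` implements a deliberately
symmetric two-functional-group ecosystem model in which both the biology
(*system symmetry*) and the environmental forcing (*environmental
symmetry*) can be made asymmetric by a single knob each, so that the
mapping from system/environmental asymmetry to response asymmetry can be
measured.

The model couples cyanobacteria (`N_CB`, producing oxygen) and
sulfur-reducing bacteria (`N_SB`, producing sulfide), competing for
phosphorus `P` and each inhibited by the other group's substrate:

    dN_CB/dt = g(P) h_S(S) N_CB − m N_CB
    dN_SB/dt = g(P) h_O(O) N_SB − m N_SB
    dO/dt    = p_O g(P) h_S(S) N_CB − c O S + α_O (O_b − O)
    dS/dt    = p_S g(P) h_O(O) N_SB − c O S + α_S (S_b − S)
    dP/dt    = −(1/y_P) g(P) [h_S(S) N_CB + h_O(O) N_SB] + α_P (P_b − P)

with Monod growth `g(P) = g_max P/(k_P + P)` and Haldane-type inhibition
`h_X = 1/(1 + X/H_X)`. Under the symmetric parameterization
(`symmetric_parameters()`: equal half-inhibition constants, production
constants and backgrounds for the two groups) the equations are invariant
under the swap (N_CB, O, α_O) ↔ (N_SB, S, α_S).

The two environmental drivers are the oxygen and sulfide diffusivities
`α_O` and `α_S` (first-order exchange rates with fixed background pools).
Stable states are found with a stepwise "temporal approach": `α_O` is
moved across 10⁻²–10⁰ h⁻¹ on a log grid while `α_S` moves the opposite
way, the system is integrated 10⁶ h at each step (with an immigration
rescue of 1 cell L⁻¹ per group every 1000 h), and the end state of each
step seeds the next. Two independent runs — one per direction of change —
trace the two branches of the hysteresis loop. Tipping points are located
as the maximum state change between consecutive gradient steps, and
response symmetry is quantified by comparing the total (oxygen + sulfide)
shift magnitudes of the two directions.

Asymmetry knobs:

* **system**: the oxygen half-inhibition constant `H_O` of the sulfur
  reducers (100 μM is symmetric; scanned 30–170 μM);
* **environment**: a factor scaling the log-width of the sulfide
  diffusivity range about its midpoint 10⁻¹ (1 is symmetric; 0 freezes
  `α_S`; 2 doubles the change).

## Worked example

```r
library(symtip)

h <- run_hysteresis(symmetric_parameters(), factor = 1,
                    settings = sim_settings(), n_steps = 41)
report <- analyze_hysteresis(h)
report
#> Response-symmetry report (metric: log10 )
#>   anoxic->oxic: Tipping point (anoxic_to_oxic): a_O = 0.1334 (log10 -0.875), magnitudes O 1.030, S 1.248 (log10), total 2.278
#>   oxic->anoxic: Tipping point (oxic_to_anoxic): a_O = 0.07499 (log10 -1.125), magnitudes O 1.248, S 1.030 (log10), total 2.278
#>   magnitude asymmetry (down - up): -0.0000
#>   bistability width: 0.250 log10 units

post_shift_plateau(h$toward_oxic, report$tp_anoxic_to_oxic, "O")
#> [1] 105.8688
```

Read: increasing oxygen diffusivity tips the system from anoxic to oxic
at α_O ≈ 0.13 h⁻¹; decreasing it tips back at α_O ≈ 0.075 h⁻¹ — that gap
is the hysteresis. The two directions' total shift magnitudes are equal
to machine precision (perfect response symmetry), and the substrate that
rises at a shift plateaus at ~106 μM in either direction. Asymmetric
configurations are one argument away:

```r
run_hysteresis(update_parameters(symmetric_parameters(), H_O = 60), factor = 1)
run_hysteresis(symmetric_parameters(), factor = 0.6)
scan_system_asymmetry(seq(30, 170, 10))          # H_O sweep
scan_environmental_asymmetry(seq(0, 2, 0.25))    # driver-range sweep
```

`plot(h)` draws the hysteresis diagram; `run_temporal()` integrates a
three-ramp driver schedule for time-series views of the shifts.

A command-line interface wraps the same functions
(`inst/cli/symtip run-hysteresis --factor 0.6 --out-dir out/`,
`... scan --type system --grid 30:170:10`, `... show-defaults`); all
outputs are CSV/JSON next to a manifest capturing the full resolved
configuration.

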