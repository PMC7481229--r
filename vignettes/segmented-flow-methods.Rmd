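---
title: "Modelling segmented-flow droplet injection at pulsed XFELs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling segmented-flow droplet injection at pulsed XFELs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segflow)
```

## The problem

Serial femtosecond crystallography (SFX) at an X-ray free-electron laser
collects one diffraction snapshot per pulse from a stream of protein
microcrystals. Burst-mode machines such as the EuXFEL fire trains of
pulses (here 32 pulses spaced 889 ns, trains repeating at 10 Hz), so a
continuously flowing jet is probed during well under 0.1% of wall-clock
time — almost all of the crystal suspension is wasted. Segmenting the
aqueous crystal suspension into sub-nL droplets separated by an
immiscible fluorinated oil lets the oil carry the jet between trains
while the crystals are concentrated into the probed plugs.

`segflow` implements the quantitative pieces of this delivery scheme:
the T-junction droplet-generation frequency model and its prefactor
fit, the pulse-train timing arithmetic, the plug-flow hit-fraction
model, a Monte Carlo droplet–pulse overlap simulator, droplet-detector
trace analysis, and continuous-versus-segmented consumption accounting,
plus synthetic-data generators that stand in for bench and beamtime
measurements.

## The frequency model

Droplets shear off at a T-junction where a cylindrical aqueous channel
meets the rectangular oil channel. In the transitional regime between
squeezing and dripping (capillary number around $10^{-2}$) the
generation frequency follows

$$f_d = \frac{K\,\mathrm{Ca}^{4/3}}{W}\cdot\frac{v_d}{v_{tot}},
\qquad \mathrm{Ca} = \frac{\eta\,v_c}{\sigma},$$

with $W$ the oil-channel width, $v_d$, $v_c$ the dispersed and
continuous superficial velocities, $v_{tot}$ their sum, $\eta$ the oil
viscosity, $\sigma$ the interfacial tension, and $K$ a prefactor
characteristic of the device, obtained by fitting. For the
fluorinated-oil system bundled as `pfd_pfo_preset()`
($\eta$ = 13.3 mPa s, $\sigma$ = 12 mN/m, 100 × 75 µm main channel) the
fitted prefactor is 3.7 m/s.

**Velocity convention.** Both phase velocities are superficial
velocities through the main-channel cross-section $A = W \times
\text{depth}$, so $v_d/v_{tot}$ equals the flow-rate ratio
$Q_{aq}/Q_{tot}$ exactly. This makes the frequency model's ratio and
the hit-fraction model's aqueous fraction the same quantity, which is
the only self-consistent reading; the velocity convention of the
original frequency-scaling work is not recorded in our sources, so this
is a design choice, stated rather than hidden.

Two regimes appear in the characterisation: the bench characterisation
grid spans total velocities of 10–20 mm/s, while beamtime total flows
of 8–50 µL/min through the same cross-section imply 18–110 mm/s. The
package does not reconcile these; both are representable, and
`flow_condition()` reports whatever the flows imply.

### Fitting the prefactor

`fit_prefactor()` performs zero-intercept least squares of measured
frequency on the regressor $x/W$, $x = \mathrm{Ca}^{4/3} v_d/v_{tot}$
(the model has no intercept). Each characterisation point is derived
from counting 60–80 droplets, so the per-point standard deviation
scales like $f/\sqrt{n}$; the default weights are therefore
$n_{droplets}/f^2$, with an unweighted fit available. A 200-replicate
recovery study in the test suite checks both the bias (mean within 1%
of the generating value) and the calibration of the reported standard
error (empirical spread within a factor two of it).

### Planning flows for a target frequency

`solve_flow_for_frequency()` inverts the model at a fixed
aqueous-to-oil flow ratio with a bracketed scalar search on total flow
(0.01–1000 µL/min, relative tolerance $10^{-6}$); the frequency is
strictly increasing in total flow at fixed ratio, so the root is unique
when the target is reachable. One droplet per 10 Hz train corresponds
to a composite term $x = fW/K \approx 2.7\times10^{-4}$; single-pulse
facilities from 30 to 120 Hz are likewise reachable
(`plan_injection()` assembles the full plan: flows, droplet volume,
plug dwell time, train coverage, predicted hit fraction, and the
sample saving $1 - p_{aq}$ relative to continuous injection).

## Timing and duty cycle

`pulse_schedule()` captures the burst structure. For the EuXFEL preset
the first two pulses of each train are detector-calibration pulses, and
every second remaining pulse is recorded, giving in-train pulse ids 3,
5, …, 31 — 15 patterns per train (pulse 32 is never recorded under
this scheme). Two numerical conventions are worth stating:

* the intra-train spacing is taken as the printed 889 ns, although the
  quoted 1.1 MHz repetition rate implies 909 ns; the explicit spacing
  wins and the discrepancy is noted here;
* a train's duration is first-pulse-to-last-pulse,
  $(n-1)\times$ spacing ≈ 27.6 µs for 32 pulses — the "~30 µs" of
  common parlance at one significant figure.

`continuous_waste_fraction()` is the complement of the train duty
cycle, ≈ 99.97% for the burst preset. Single-pulse machines are
modelled as one-pulse trains with an instantaneous-pulse convention
(waste fraction 1); pass `probe_window_s` for a refined estimate with a
finite effective probe window.

## Jet geometry and the hit fraction

A gas-focused jet's speed is pinned by the sheath-gas pressure drop, so
mass conservation sets the radius: $r_j = \sqrt{Q_{tot}/(\pi v_j)}$
(about 2.5 µm at 16.5 µL/min and 14 m/s). Under a plug-flow picture of
the segmented jet — plugs advect rigidly, no deformation, coalescence
or axial dispersion — the expected number of crystals illuminated per
pulse is

$$\langle N \rangle = \pi r_j^2\, D_b\, n\, p_{aq}
 = \frac{D_b\, n\, Q_{aq}}{v_j},$$

linear in the aqueous flow rate at fixed jet speed and beam. Both
algebraic forms are implemented (`mean_hit_fraction()`,
`hit_fraction_flow_form()`) and tested to agree to machine precision.
Two caveats are deliberately surfaced instead of smoothed over:

* a commonly quoted reduced form that drops the $1/v_j$ factor is
  dimensionally inconsistent; the implementation keeps the full
  expression;
* nominal crystal densities of ~5 × 10⁹ crystals/mL for 8–10 µm
  crystals are physically impossible (the implied solid fraction
  exceeds 1), so the density $n$ is treated as a free calibration
  parameter, default-free on purpose.

The beam is a single scalar diameter (default 20 µm for a 15 × 20 µm²
focus); an elliptical refinement would use the width transverse to the
jet. The default jet speed is 50 m/s, the replenishment requirement
between MHz-spaced pulses; the achieved speed is generally not
measured, so it is overridable everywhere it enters.

`plug_geometry()` converts a droplet volume and the flows into plug
dwell times at the interaction point ($V_d/Q_{tot}$ for the aqueous
plug); one aqueous + oil pair spans exactly one generation period, and
the aqueous share of the period is $p_{aq}$ exactly. Typical operating
combinations give 100–500 µs plugs against a ~28 µs train — but note
that not every combination of the quoted volume and flow ranges lands
in that window; the range describes typical operation, not a bound.

## The Monte Carlo simulator

`simulate_injection()` plays the alternating plug timeline against the
pulse times. Choices that matter:

* **Phase.** Droplet generation is not synchronised with the X-ray
  clock. Plug periods (tens of ms) are comparable to the 100 ms train
  period and the two clocks are uncorrelated, so the plug phase is
  drawn uniformly on one period *independently per train*. This is
  what makes the per-train aqueous indicator Bernoulli($p_{aq}$) and
  the binomial convergence test meaningful. A fixed `phase_s` switches
  to coherent mode, which `synchronized_mode()` uses to centre one
  plug on every train; with a plug at least as long as the train span,
  100% of recorded pulses are aqueous.
* **Hits.** Crystal occupancy is Poisson with the model mean,
  independent across pulses — the simplest law consistent with the
  mean hit fraction.
* **Boundary zone.** A pulse within `interface_window_s` of a phase
  transition is labelled `boundary` (neither pure aqueous nor oil),
  mirroring the rare oil scattering rings attributed to hitting a
  droplet's leading or trailing edge. Default 0.
* **Jitter.** Optional lognormal plug-period multiplier with given CV,
  default off (generation is stable after equilibration). Within a
  train the timeline is locally periodic; a ~30 µs train against ~50 ms
  plugs makes intra-train drift negligible.

One consequence of the model worth stating plainly: with equal
per-aqueous-pulse hit mean, *unsynchronised* segmented flow does not
beat continuous injection per µL (hits per µL is flow-independent
under the hit-fraction model); the gain of the idealised
*synchronised* limit is the full $Q_{tot}/Q_{aq}$ factor, asserted on
constructed cases in the tests. Observed beamtime gains for
unsynchronised operation therefore contain physics beyond this model
(e.g. crystal behaviour in plugs versus a continuous stream).

`consumption_report()` does the run-accounting arithmetic: hits/µL per
condition, fold change against a reference, and percent reduction in
consumption *rate* (volume per minute), which for matched durations
reduces exactly to $100(1 - V/V_{ref})$.

## Trace analysis

The in-line droplet detector yields a two-level voltage trace as oil
and aqueous plugs alternately cross a 1550 nm beam.
`detect_droplets()` thresholds at the midpoint of the 10th/90th
percentile levels with a hysteresis band of 20% of the level
separation and a minimum dwell of 3 samples (all configurable);
frequency is aqueous-event starts per unit time. The estimate is
invariant to offset and gain of the voltage. Which level is aqueous is
a configuration: the default assumes water transmits *less* at
1550 nm (water absorbs there) — an assumption, documented, not a
measurement. Constant traces return a flagged empty result, not an
error. Oscilloscope sampling rate and amplitude are nowhere specified,
so the synthetic defaults (10 kHz, 1 V swing) are arbitrary but
harmless: everything downstream is level- and rate-agnostic.

`panel_horizontal_profile()` reproduces the diffuse-scattering check:
row-wise sums (a projection, not a mean) of panel images averaged over
a stack, with a ring score = prominence of the profile maximum in a
row band over the median level outside it. Co-flowing oil produces a
strong ridge; droplet injection does not.

## Synthetic data: what it does and does not show

The generators (`make_frequency_dataset()`, `make_trace()`,
`make_hit_stream()`, `make_panel_stack()`) emulate the statistical
structure the analyses assume: frequency measurements with 5%
multiplicative Gaussian noise (or a counting mode that jitters
individual droplet periods, giving errors ~$cv/\sqrt{n}$), 60–80
droplets counted per point, two-level traces with finite rise time and
Gaussian noise, Poisson hit streams, and flat panels with an optional
Gaussian ridge. The default characterisation design is a 10 × 7 grid —
total velocity 10–20 mm/s crossed with aqueous fractions 0.15–0.5,
bracketing the flow-ratio combinations used in practice.

What passing tests on these fixtures shows: the estimators recover
what generated the data, at the stated noise, with calibrated errors.
What they do not show: that real devices obey the frequency law
outside the characterised regime, that real crystal occupancy is
Poisson, that real traces are two-level with stationary noise, or
anything about diffraction data quality. Experimental hit counts,
indexing rates and structure quality are outside what desk-scale
simulation can reproduce and are not claimed.

## Problem sizes and numerical choices

Simulations in the tests and drivers use up to $10^5$ pulses,
$\le 10^5$ trace samples and small (64 × 128) panels — sizes chosen so
every statistical check has comfortable power while a full run stays
in the seconds-to-a-minute range. Stochastic assertions use fixed
seeds and 3σ bands from the analytic sampling law of the quantity
under test. Root finding brackets 0.01–1000 µL/min; degenerate inputs
(no oil, constant trace, single measurement, empty image stack) are
either typed results with diagnostic flags or immediate, named errors,
never silent NA propagation.
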