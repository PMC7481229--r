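# segflow

Modelling and simulation of **segmented-flow (aqueous-droplet-in-oil)
sample injection** for serial femtosecond crystallography at pulsed
X-ray free-electron lasers.

Burst-mode XFELs deliver X-ray pulses in short trains (e.g. 32 pulses
spaced 889 ns, trains repeating at 10 Hz), so a continuously flowing
microjet of crystal suspension is probed during less than 0.03% of
wall-clock time and >99% of precious protein sample is wasted.
Segmenting the aqueous crystal suspension into sub-nL droplets
separated by an immiscible fluorinated oil concentrates crystals into
the plugs that meet the pulses. `segflow` provides the quantitative
toolkit for designing and analysing such experiments:

* **Droplet generation** — the T-junction frequency model
  `f_d = K·Ca^(4/3)/W · v_d/v_tot` with capillary number
  `Ca = η·v_c/σ`: forward prediction, weighted zero-intercept
  prefactor fitting, flow-rate solving for a target frequency, droplet
  volumes (`droplet_frequency`, `fit_prefactor`,
  `solve_flow_for_frequency`, `droplet_volume`).
* **Beam timing** — pulse-train schedules, recorded-pulse masks and the
  continuous-injection waste fraction, with presets for burst-mode and
  single-pulse facilities (`pulse_schedule`, `facility_preset`,
  `recorded_pulse_ids`, `continuous_waste_fraction`).
* **Hit fraction** — jet radius from flow and jet speed, and the
  plug-flow expectation `⟨N⟩ = π r_j² D_b n p_aq = D_b n Q_aq / v_j`
  (`jet_params`, `mean_hit_fraction`, `plug_geometry`, `spans_train`).
* **Monte Carlo injection** — droplet–pulse overlap simulation with
  random or locked phase, Poisson crystal occupancy, boundary zones and
  period jitter; run summaries and continuous-vs-segmented consumption
  reports (`simulate_injection`, `synchronized_mode`, `summarize_run`,
  `consumption_report`).
* **Trace & panel analysis** — two-level droplet-detector trace
  segmentation with hysteresis, and horizontal diffuse-scattering
  profiles of detector panels with an oil-ring score
  (`detect_droplets`, `compare_to_model`, `panel_horizontal_profile`).
* **Synthetic data** — seeded generators for every input the pipeline
  consumes (`make_frequency_dataset`, `make_trace`, `make_hit_stream`,
  `make_panel_stack`).

The numbered scripts under `analysis/` run the full workflow
(frequency characterisation and fit, timing accounting, injection
simulation and consumption comparison, trace/panel analysis) and write
their tables to `results/`.

## Worked example

```r
library(segflow)

fluid <- pfd_pfo_preset()       # η = 13.3 mPa s, σ = 12 mN/m, W = 100 µm
eu <- facility_preset("euxfel") # 10 Hz × 32 pulses, 889 ns spacing

# Fit the prefactor from a synthetic bench characterisation
dat <- make_frequency_dataset(fluid, k_true = 3.7, noise_cv = 0.05, seed = 1)
fit <- fit_prefactor(dat, fluid)
fit
#> <prefactor_fit>
#>   K = 3.682 +/- 0.020 m/s (70 points, weighted)

# Tune droplet generation to one droplet per pulse train (10 Hz)
plan <- plan_injection(fluid, k = 3.7, facility = "euxfel", flow_ratio = 0.3)
plan
#> <injection_plan>
#>   target 10 Hz: Q_aq = 0.771, Q_oil = 2.57 uL/min
#>   droplet 1.29e+03 pL, plug 2.31e+04 us, spans train: TRUE
#>   sample saving vs continuous: 77%

# How much does continuous injection waste?
continuous_waste_fraction(eu)
#> [1] 0.9997244

# Run accounting: continuous vs segmented injection
tab <- read.csv(system.file("extdata", "run_accounting.csv",
                            package = "segflow"))
consumption_report(tab, "continuous")[, c("label", "hits_per_ul",
                                          "fold_change",
                                          "percent_reduction")]
#>              label hits_per_ul fold_change percent_reduction
#> 1       continuous    2.219231    1.000000           0.00000
#> 2 segmented_subset    6.681818    3.010871          57.69231
#> 3    segmented_all    5.997921    2.702703          28.20896
```

The fitted prefactor recovers the generating 3.7 m/s within its
standard error; the waste fraction says 99.97% of a continuous jet
passes unprobed; and the accounting table shows segmented injection
collecting ~3× more hits per µL of crystal suspension than continuous
injection, a ~58% reduction in consumption over the matched 26-minute
comparison.

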