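# rumidyn

Simulation and calibration of a system-dynamics model of adolescent
depression in which depressive symptoms, rumination, and *past stressors
kept alive* reinforce one another.

## The problem and who this is for

Response-styles theory proposes that rumination contributes to depression
partly by keeping past stressors "alive" — the individual stays activated
long after the event has ended. `rumidyn` implements an individual-level
stock-flow model of that mechanism for researchers in computational
psychiatry and epidemiological modelling who want to simulate symptom
trajectories, test estimation strategies on synthetic cohorts, or explore
intervention leverage points (e.g., what a rumination-focused treatment
that shortens memory time would do).

Three stocks evolve in continuous time — depressive symptoms `D` (CDI
scale, 0–52), rumination `R` (0–39), and past stressors kept alive `S`
(events). Rumination and depression adjust toward linear indicated values
with first-order delays:

    dR/dt = (θ1 + θ2·D + θ3·G + θ4·S + θ5·R + εR − R) / τR
    dD/dt = (θ6 + θ7·R + θ8·D + εD − D) / τD
    dS/dt = u − S / M(R),      M(R) = max(θ9·R, M_min)

with `G = 1` for girls, constant ongoing-stressor inflow `u`
(events/month), and first-order autocorrelated process noise `εR`, `εD`
(stationary SDs θ10, θ11, correlation time θ12). Memory time `M` grows
with rumination, closing the reinforcing loop stressors → rumination →
memory time → stressors; θ2/θ7 close the rumination ↔ depression loop.
Default parameters are published indirect-inference estimates from a
three-wave study of 661 adolescents. The combined loop gain
`g = θ5 + θ2·θ7/(1−θ8) + θ4·u·θ9` exceeds 1 for `u` above ≈1.1
events/month, beyond which symptoms grow until the instrument ceiling.

The package provides:

* a vectorised Euler–Maruyama simulator with analytic steady-state and
  loop-gain oracles (`simulate_profiles()`, `steady_state()`),
* a synthetic three-wave cohort generator matched to the published
  instrument moments (`cohort_spec()`, `sample_profiles()`,
  `generate_panel()`),
* an indirect-inference calibrator with common random numbers and
  parametric-bootstrap standard errors (`calibrate_model()`,
  `bootstrap_se()`, broom-style `tidy()`/`glance()`),
* experiment engines: memory-time summaries, 2⁴ factorial trajectory
  ensembles with 75% envelopes, and terminal-symptom sensitivity grids,
  each with an `autoplot()` method.

## Worked example

```r
library(rumidyn)
params <- model_params()          # published estimates (Table-2 defaults)

# Where does an average girl with mean stressor exposure end up?
steady_state(params, "girl", inflow = 4.97 / 6)
#> # A tibble: 1 × 8
#>   gender inflow     D     R     S     M loop_gain divergent
#>   <chr>   <dbl> <dbl> <dbl> <dbl> <dbl>     <dbl> <lgl>
#> 1 girl    0.828  9.90  10.3  12.6  15.2     0.739 FALSE

# Interpretation: symptoms settle at ~9.9 (below the clinical cut of 16),
# rumination at ~10.3, and a stressor stays "alive" ~15 months. At high
# ongoing stress the loop gain crosses 1 and no finite equilibrium exists:
steady_state(params, "girl", inflow = 1.875)$loop_gain   # 1.128 -> divergent

# Memory-time experiment on a synthetic cohort (353 girls, 308 boys):
profiles <- sample_profiles(cohort_spec(), seed = 1)
memory_time_summary(profiles, params, horizon = 7, seed = 1)
#> # A tibble: 3 × 6
#>   group              mean_girls mean_boys n_girls n_boys  p_value
#>   <chr>                   <dbl>     <dbl>   <int>  <int>    <dbl>
#> 1 all                      15.1      10.1     353    308 1.55e-15
#> 2 depressed_high_rum       27.0      16.6      40     12 1.04e- 4
#> 3 depressed_low_rum        24.4      14.5      25     23 7.53e- 6
```

Girls hold on to stressors several months longer than boys (Welch p ≪
0.05) because the gender coefficient θ3 raises their rumination, which
lengthens memory time — the central asymmetry the model was built to
quantify. Initially depressed, high-rumination individuals keep stressors
alive the longest.

Factorial trajectory ensembles and the sensitivity contour:

```r
groups <- factorial_levels("girl")            # 16 profiles, mean ± SD levels
sc <- run_scenario(groups[1, ], params, seed = 1)   # 2,500 noisy replicates
autoplot(sc)                                  # mean + 75% envelope vs months

grid <- sensitivity_grid(params, n_rep = 100, seed = 1)
autoplot(grid)                                # terminal D by R0 x inflow
```

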