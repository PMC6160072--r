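---
title: "A stock-flow model of depression, rumination, and stressors: model, calibration, and experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stock-flow model of depression, rumination, and stressors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumidyn)
```

## The model

`rumidyn` simulates an individual-level system-dynamics model of adolescent
depression built around two reinforcing feedback loops. Three stocks evolve
in continuous time:

* $D(t)$ — depressive symptoms on the CDI scale (0–52),
* $R(t)$ — rumination on a rescaled response-styles subscale (0–39),
* $S(t)$ — *past stressors kept alive*, in life-event units ($\ge 0$).

The rumination and depression stocks chase linear *indicated values* with
first-order adjustment times $\tau_R$ and $\tau_D$ (months):

$$
\dot R = \frac{\theta_1 + \theta_2 D + \theta_3 G + \theta_4 S + \theta_5 R
  + \varepsilon_R - R}{\tau_R}, \qquad
\dot D = \frac{\theta_6 + \theta_7 R + \theta_8 D + \varepsilon_D - D}{\tau_D},
$$

where $G$ is 1 for girls and 0 for boys. The stressor stock integrates a
constant ongoing-stressor inflow $u$ (events/month) against the *let-it-go*
outflow $S / M$, where the *memory time*

$$M(R) = \max(\theta_9 R,\ M_{\min})$$

grows with rumination: the more a person ruminates, the longer a past
stressor stays "alive". This closes the first reinforcing loop
(stressors → rumination → memory time → stressors); the mutual
$\theta_7$/$\theta_2$ coupling of rumination and depression closes the
second (symptom exacerbation). The noise terms $\varepsilon_R$,
$\varepsilon_D$ are first-order autocorrelated (Ornstein–Uhlenbeck-type)
processes with stationary SDs $\theta_{10}$, $\theta_{11}$ and correlation
time $\theta_{12}$.

Default parameter values are the published indirect-inference estimates for
a cohort of 661 adolescents (`model_params()`, also shipped as
`inst/extdata/table2_defaults.json`).

### Reconstruction choices

The original supplementary equation listing is not publicly archived, so the
functional forms above are a reconstruction with the following commitments,
chosen for self-consistency with the published parameter table and cohort
moments and then frozen:

* $\theta_5$ and $\theta_8$ are self-coefficients *inside* the indicated
  values, so the continuous model and the discrete-time autoregressive
  reading share the fixed point $D^\* = (\theta_6 + \theta_7 R)/(1 -
  \theta_8)$ — about 10.7 at the cohort mean rumination of 11.59, in line
  with observed mean CDI scores of 9.5–9.8.
* $\tau_R = \tau_D = 1$ month, so one model month corresponds to one step
  of the companion estimation model. Both are exposed in the parameter
  object.
* Noise enters the indicated values, not the stocks, so noise-free steady
  states are exact and analytically checkable (`steady_state()`).
* Stocks are clamped to instrument ranges ($D \in [0,52]$, $R \in [0,39]$,
  $S \ge 0$). The rumination scale is the 13-item subscale minus its
  13-point floor, which is how reported means of ~11.6 fit a 0–39 range.
* $M_{\min} = 0.25$ months keeps the outflow bounded as $R \to 0$; released
  stressors cannot leave faster than the roughly weekly recall scale of the
  instruments.

### Loop gain and divergence

With constant $u$ the noise-free system is linear. Around the fixed point
the combined gain of the two loops is

$$g = \theta_5 + \frac{\theta_2 \theta_7}{1 - \theta_8}
  + \theta_4\, u\, \theta_9 .$$

At the default parameters $g$ crosses 1 near $u \approx 1.1$ events/month;
`steady_state()` reports the gain and flags divergence, in which case
trajectories grow until the instrument clamps bind. The girls' high-inflow
factorial cells sit in this divergent regime ($g = 1.128$ at $u = 1.875$).
In that regime the rumination ceiling ($R = 39$) binds first, which pins
depressive symptoms at the clamped conditional equilibrium
$(\theta_6 + 39\,\theta_7)/(1-\theta_8) \approx 28$ — the saturation level
the divergent trajectory ensembles settle at.

## Numerical scheme

Integration is explicit Euler(–Maruyama) with `dt = 0.125` months, the
system-dynamics convention; the constructor enforces
`dt <= min(tau_R, tau_D, theta12)/4`. Halving `dt` moves noise-free
trajectories by less than 1% (tested).

The noise update uses the Euler decay factor $\phi = 1 - \Delta t/\theta_{12}$
with innovation SD $\sigma\sqrt{1-\phi^2}$. This matches the stationary
variance *exactly* at any step size — the naive Euler–Maruyama innovation
$\sigma\sqrt{2\Delta t/\theta_{12}}$ overstates the stationary SD by about
2% at the default step — while the lag-$\Delta$ autocorrelation
$\phi^{\Delta/\Delta t}$ agrees with $e^{-\Delta/\theta_{12}}$ to first
order (0.522 vs 0.535 at a one-month lag). Noise states start from their
stationary distribution so replicate ensembles are stationary from month 0;
this keeps the 75% envelope calibrated from the first month rather than
after a burn-in.

Simulation over a cohort is vectorised across individuals; one RNG stream
keyed by a child seed drives the whole noise matrix, so results are
deterministic given `(inputs, seed)`. Multi-stream computations derive
per-stream seeds with `child_seed(master, k)` (a Lehmer-style map modulo
$2^{31}-1$); a `seed` column on a profile table gives any single individual
a stream of their own.

## The synthetic cohort

No individual-level data are deposited, so `cohort_spec()` +
`sample_profiles()` + `generate_panel()` emulate the study design: 353
girls and 308 boys, initial conditions drawn from truncated normals at the
published wave-1 means/SDs per gender, three assessment waves at months 0,
4, and 7 with rumination observed at all three and depression/stressor
counts at waves 1 and 3 only, scores rounded to integers and clipped to
instrument ranges.

Choices where the study reports nothing:

* Initial conditions are independent across variables (a Gaussian copula
  correlation matrix is exposed, identity by default) — only marginal
  moments are published.
* Each individual's constant inflow is their wave-1 checklist count divided
  by six months, because the checklist asks about events "in the past six
  months"; the initial stock $S_0$ equals the checklist count itself. Both
  conventions are configurable (`inflow_rule`, `s0_scale`). These two
  conventions dominate the *level* of simulated memory times (see
  Limitations).
* Measurement noise defaults to zero; the estimation treats process noise
  only.

What the generator does *not* emulate: attrition, episodic (non-constant)
stressor arrival, cross-sectional heterogeneity in the behavioural
parameters, and any baseline correlation structure. Tests passing on these
cohorts therefore validate the machinery and the model's internal logic,
not goodness-of-fit to real adolescents.

## Calibration by indirect inference

`aux_stats()` reduces a panel to 36 auxiliary statistics: per-gender means
and sample SDs of rumination (waves 1–3) and of depression and stressors
(waves 1 and 3), plus eight pooled cross-wave/cross-construct correlations.
These are the moments a three-wave design identifies.

`calib_objective()` is the weighted quadratic form
$(\hat s_{\mathrm{sim}}(\theta) - \hat s_{\mathrm{emp}})^\top W
(\hat s_{\mathrm{sim}}(\theta) - \hat s_{\mathrm{emp}})$ with $W$ diagonal,
set to inverse bootstrap variances of the empirical statistics
(`aux_weights()`, 500 stratified nonparametric replicates by default).
Simulation conditions on the panel's own wave-1 records
(`panel_profiles()`), and every evaluation reuses the same seed set
(common random numbers) over `n_sim = 5` synthetic cohort copies, so the
objective is deterministic in $\theta$ and exactly zero when the
"empirical" panel was produced by the same pipeline and seeds. Because
wave-1 records are conditioned on, the wave-1 statistics contribute zero;
they remain in the vector to keep its layout fixed.

`calibrate_model()` minimises this objective with restarted Nelder–Mead
(Brent for a single free parameter); out-of-bounds proposals get a penalty
value rather than an error. `bootstrap_se()` re-simulates panels at the
estimate and re-estimates each (parametric bootstrap). Parameter-recovery
experiments on synthetic cohorts of ~5,000 recover the symptom-exacerbation
coefficients $\theta_7$, $\theta_8$ and the memory-time coefficient
$\theta_9$ within ±25%, with $\theta_7$/$\theta_8$ recovered far more
tightly than $\theta_9$ in absolute terms — the same ordering the published
standard errors show. The test suite runs this at 5 replicate panels, 2
optimizer starts, 150 simplex iterations, and 3 cohort copies per
evaluation; these sizes were chosen as the smallest at which the recovery
distribution is stable.

## Experiments

* `memory_time_summary()` — per-individual time-average of $M(t)$ over the
  7-month study horizon (every integration step, unweighted, including
  month 0), summarised for all girls/boys and for initially depressed
  individuals ($D_0 > 16$) split at the published rumination mean cut of
  11.59 (fixed, not recomputed), with Welch t-tests for the gender
  contrast.
* `factorial_levels()` + `run_scenario()` — the $2^4$ design over high/low
  $D_0$, $R_0$, $S_0$, and inflow (mean ±1 SD for the scores; mean +2 SD
  vs 0 for the stressor quantities), 2,500 replicates per group over 120
  months, summarised monthly by mean, 12.5th/87.5th percentiles (type-7
  linear interpolation; the published estimator is unstated), and the
  fraction above the clinical threshold of 16.
* `sensitivity_grid()` — mean terminal symptoms at month 120 over an
  initial-rumination × inflow grid with $D_0$ and $S_0$ pinned at the
  girls' means.

## Known limitations

Two families of published numbers are not reproduced at their printed
values, and the discrepancies are informative about the unavailable
supplementary equations rather than about defects in the machinery:

* **Memory-time levels.** With inflow = checklist/6, simulated mean memory
  times run high: girls land within the wide reconstruction tolerance of
  the printed 11.7 months, but boys (≈10 vs 6.8) and especially the
  depressed low-rumination girls (≈16–20 vs 9.3) overshoot. The printed
  table is internally consistent with a much smaller effective inflow of
  *kept-alive* stressors (the original work estimated that inflow
  separately) and with rumination *declining* for depressed low-rumination
  individuals, whereas the reconstructed $\theta_2 D$ feedback pushes it
  up when $D_0 > 16$. The qualitative structure — girls ≫ boys, high-rum ≫
  low-rum ≫ boys-low — reproduces decisively.
* **Factorial transients.** At the all-high corner the indicated rumination
  (≈14.4) lies below $R_0 = 20.49$, so rumination relaxes downward while
  the stressor stock builds slowly; the ensemble mean dips for roughly a
  year before the divergent loop takes over. The published trajectories
  rise from the start, and initially-high vs initially-low symptom groups
  re-converge within ~20 months there versus ~100 here. These shapes are a
  structural consequence of the published parameter values under the
  linear first-order reconstruction, which the steady-state oracle pins
  down exactly — they cannot be altered without breaking the quantities
  that do verify.

Smaller caveats: the baseline correlation structure of the initial
conditions is assumed independent; stressor arrival is a constant flow, so
single-subject trajectories lack the episodic spikes of real life-event
histories; and all parameters are population-level, so between-person
variation enters only through initial conditions and noise realizations.
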