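# omrkit

Analysis of the larval zebrafish optomotor response (OMR) and of
trial-structured calcium imaging across anesthesia and washout — together
with closed-loop behavioral and imaging simulators, so that every analysis
stage runs against data with known ground truth.

## The problem

Larval zebrafish turn and swim to follow whole-field visual motion. Two
families of measurements quantify how this behavior and its neural circuitry
emerge and recover around anesthesia:

* **Behavior.** Freely swimming fish are tracked at 100 Hz while gratings
  (static 5 s, moving 10 s at 1 cm/s, static 5 s) are presented in randomized
  sets of five conditions (none / forward / backward / left / right), 30 sets
  per fish. Swimming is bout-structured; the key statistics are the turn-angle
  distribution, the proportion of "correct" turns (sign of the turn matches
  the stimulus direction; positive angles = leftward), the bout rate (0.5 Hz
  at rest, 1 Hz during motion), the cumulative turn angle, and the recovery of
  the bout rate after acute anesthesia, `r(t) = r_inf (1 − e^{−(t−t0)/τ})`
  with τ ≈ 25 min.
* **Imaging.** Small units (1–5 similarly tuned neurons) are imaged at 1 Hz
  over hour-long blocks (baseline / tricaine / washout…), 60-s trials with
  30 s of leftward or rightward motion. The response metric is **C − C0**
  (trial fluorescence minus the mean of the 10 pre-motion frames; subtraction,
  not division, because C0 is often zero). Per unit, the **responsiveness
  index** normalizes trial responses by the unit's maximum absolute response
  (net-increasing units peak at +1, net-decreasing at −1), and the
  **direction-selectivity index** (DSI) differences adjacent left-then-right
  trial pairs and normalizes to [−1, +1] (+1 = leftward-selective). Units
  whose C − C0 never exceeds 100 are excluded from kinetics fitting; onset and
  offset time constants and logistic recovery midpoints
  `A/(1 + e^{−(t−x0)/k})` are fitted per unit.

Group statistics are medians with interquartile ranges, two-sided
Kolmogorov–Smirnov / Mann–Whitney / Kruskal–Wallis tests, and effect sizes as
absolute median differences in native units.

The package implements all of the above plus the two synthetic generators
(virtual closed-loop fish; trial-structured fluorescence units with
anesthesia-dependent gain). See `vignettes/omrkit-methods.Rmd` for the models
and every fixed convention.

## Worked example

```r
library(omrkit)
library(dplyr)

# six control fish, full pipeline: simulate -> detect bouts -> metrics
sessions <- simulate_cohort(6, params = fish_params(), seed = 42)
perf <- bind_rows(lapply(sessions, session_performance))
summarize_group(perf$proportion_correct)
#> # A tibble: 1 x 4
#>       n median   q25   q75
#>   <int>  <dbl> <dbl> <dbl>
#> 1     6  0.956 0.950 0.960
```

The median proportion of correct turns (0.956 here) recovers the generator's
asymptotic turn accuracy (0.967) up to the within-trial evidence-accumulation
transient; per-fish bout rates land on 1 Hz during motion and 0.5 Hz at rest.

```r
# an acute-anesthesia imaging experiment: 20 units, 5 blocks
sched <- build_block_schedule("acute", n_washout_blocks = 3, seed = 1)
units <- sample_unit_population(20, "acute", seed = 2)
pop   <- simulate_unit_population(units, sched, seed = 3)
resp  <- trial_responses(segment_trials(population_frames(pop), sched))
dsi_series(resp) |>
  group_by(unit_id) |>
  summarise(dsi = median(dsi)) |>
  left_join(units[, c("unit_id", "tuning")], by = "unit_id") |>
  head(5)
#>   unit_id     dsi tuning
#> 1 u001     0.882  left_selective
#> 2 u002    -0.0517 motion_selective
#> 3 u003    -0.844  right_selective
#> 4 u004     0.655  left_selective
#> 5 u005     0.0900 suppressed
sum(filter_fittable(resp)$fittable)
#> [1] 15
```

Median DSI signs recover each unit's ground-truth tuning; motion-selective
and suppressed units sit near zero. Fitting a noisy bout-rate recovery:

```r
t <- seq(0, 150, by = 5)
set.seed(1)
r <- pmax(0, 0.75 * (1 - exp(-t / 25)) + rnorm(length(t), 0, 0.05))
fit_exp_recovery(t, r)
#> <exp_recovery_fit> converged: TRUE
#>   r_inf = 0.751
#>   t0 = 0.319
#>   tau_min = 23.4
```

Fit objects have `tidy()`, `glance()`, and `autoplot()` methods;
`plot_turn_distribution()`, `plot_performance_curve()`, and
`plot_index_heatmap()` cover the figure-style summaries. A thin command-line
wrapper lives at `inst/scripts/omrkit.R`
(`simulate-behavior`, `analyze-behavior`, `simulate-imaging`,
`analyze-imaging`, `report`).

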