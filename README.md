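# capstates

Brain-state occupancy analysis for population neuroimaging: co-activation-pattern
(CAP) clustering of resting-state fMRI, fractional occupancy of discrete brain
states, and regression models linking occupancy to white-matter-hyperintensity
(WMH) burden and cognition.

## The scientific problem

Cerebral small vessel disease leaves an MRI footprint of white matter
hyperintensities. One hypothesis for how this diffuse injury impairs cognition
is *functional network dedifferentiation*: with growing lesion load, the brain
spends less time in its dominant, default-mode-network (DMN)-related activity
configurations. `capstates` implements the full analysis pipeline needed to
test this in a cohort:

1. **Brain states.** Parcel-level BOLD volumes from all participants are pooled
   into an `n_parcels x sum(T_i)` feature matrix and clustered with k-means
   (`k = 5`) under the correlation distance `d(x, y) = 1 - r(x, y)`,
   implemented through the identity `1 - r(x, y) = ||x - y||^2 / 2` for
   vectors standardized to zero mean and unit norm. Each cluster is a
   co-activation pattern ("brain state").
2. **Fractional occupancy.** `FO_si` is the proportion of participant *i*'s
   retained volumes assigned to state *s*. The two states with the highest
   cohort-mean occupancy are DMN-related (activation, DMN+; suppression,
   DMN−); `FO_high` is each participant's average occupancy of those two.
3. **Primary model.** A fixed-dispersion beta regression with logit link,

   `FO_high ~ logWMH+ + 1{WMH = 0} + age + sex`,   `FO_high ~ Beta(mu * phi, (1 - mu) * phi)`,

   where non-zero WMH volumes enter as natural logs, exact zeros keep the
   value 0 with a binary indicator, and the effect is reported as the odds
   ratio per interquartile ratio (Q3/Q1) of the WMH distribution.
4. **Secondary model.** A Gamma GLM with log link,
   `TMT-B ~ FO_high + logWMH+ + 1{WMH = 0} + age + sex + education`,
   reported as the multiplicative change in expected Trail Making Test B
   completion time per 5 percentage points of occupancy.
5. **Robustness and planning.** A multiverse executor re-runs the analysis
   over 9 confound-regression variants x 9 parcellations x 3 WMH components
   (243 scenarios), and a bootstrap power curve estimates the rejection rate
   of the primary test at candidate sample sizes.

The package also post-processes binary WMH segmentations (removal of
connected components below 30 voxels at 26-connectivity; voxel-wise
periventricular/deep partition at a 10 mm distance to the ventricles), and
ships a **synthetic-cohort generator** with known ground truth (zero-inflated
log-normal WMH volumes, a logit-scale occupancy-WMH link, Gamma-distributed
TMT-B times, planted state centroids), so every stage of the pipeline is
testable without access to cohort data.

## Worked example

```r
library(capstates)

cfg <- generator_config(n_participants = 1651, seed = 42)
cohort <- simulate_cohort(cfg, include_sequences = FALSE)

quality_check(cohort$occupancy)
#> High- vs low-occupancy separation: 7.7 pp (95% CI 7.3-8.2), n = 1651

run_primary(cohort)
#> Primary analysis: high-state occupancy ~ WMH burden
#>   n = 1651 complete cases (0 excluded), IQR ratio 5.17
#>   OR per 5.17-fold WMH increase: 0.95 (95% CI 0.93-0.97), P = 9.92e-07

run_secondary(cohort)
#> Secondary analysis: TMT-B ~ high-state occupancy
#>   n = 1651 complete cases (0 excluded)
#>   multiplier per 5 pp occupancy: 0.98 (95% CI 0.96-0.99), P = 0.007525
```

The quality check confirms that the two high-occupancy states are clearly
separated from the remaining three (the interval excludes zero). The primary
analysis recovers the generator's planted effect (odds ratio 0.95 per
interquartile ratio of WMH volume): each ~5-fold increase in lesion volume
lowers the odds of occupying a DMN-related state by about 5%. The secondary
analysis recovers the planted cognition link: every 5 percentage points of
occupancy multiply the expected TMT-B time by ~0.98 (i.e. occupancy loss slows
task completion).

Brain states are estimated from (here: simulated) BOLD series directly:

```r
small <- simulate_cohort(generator_config(n_participants = 40, seed = 7,
                                          n_parcels = 60,
                                          volumes_range = c(60L, 80L)),
                         include_bold = TRUE)
model <- estimate_brain_states(small$bold, k = 5, n_restarts = 10, seed = 1)
fo  <- fractional_occupancy(model)
sel <- select_high_occupancy(fo)
prof <- network_profile(model, small$config$network_labels)
subset(prof, state %in% sel$top & (sim_pos > 0.5 | sim_neg > 0.5))
#>    state network   sim_pos   sim_neg
#> 33     3 Default 0.0000000 0.9997897
#> 34     4 Default 0.9997784 0.0000000
```

The two highest-occupancy clusters are characterized by activation (DMN+) and
suppression (DMN−) of the default-mode parcels, as planted.

## Vignette

`vignettes/brain-state-occupancy.Rmd` documents the statistical models and
their assumptions, the generator's calibration, every numerical choice
(initialization, tolerances, tie-breaking, boundary and degenerate-input
policies), and known limitations.
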