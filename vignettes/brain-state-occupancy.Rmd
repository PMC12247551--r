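---
title: "Brain-state occupancy, WMH burden and cognition: models and methods"
author: "capstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-state occupancy, WMH burden and cognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `capstates`: the models
and their assumptions, the calibration of the synthetic-cohort generator, the
numerical choices behind each estimator, and the limits of what the test
suite can establish about real data.

## 1. Co-activation-pattern brain states

### Feature matrix and distance

Parcel-level, de-confounded BOLD series (one `n_parcels x T_i` matrix per
participant, repetition time 2.5 s) are pooled column-wise into a single
feature matrix; each column is one brain volume. Volumes are clustered with
k-means under the correlation distance

$$d(x, y) = 1 - r(x, y),$$

with $r$ the sample Pearson correlation across parcels. For vectors
standardized to zero mean and unit Euclidean norm this equals
$\lVert \tilde x - \tilde y \rVert^2 / 2$, so the implementation standardizes
all volumes once, runs Lloyd iterations in the standardized space, and
re-standardizes every cluster mean after each update. The re-standardized
mean is the exact minimizer of the within-cluster correlation distance for a
fixed partition (the centroid that maximizes
$\sum_i \tilde x_i^\top \tilde c$ over unit-norm, zero-mean $\tilde c$ is the
standardized mean), so each Lloyd step is a coordinate descent on the
objective. This standardized-points formulation is adopted as the canonical
behavior of the package; it is tested against exhaustive enumeration of all
two-partitions on small instances, where it attains the global optimum.

Numerical choices, none of which are pinned down by the method itself and all
of which are therefore explicit arguments with documented defaults:

* **Initialization**: `k` distinct volumes sampled uniformly per restart;
  `n_restarts = 20`, best run by inertia.
* **Convergence**: assignments stable or inertia change below `tol = 1e-6`;
  `max_iter = 300`.
* **Assignment ties**: the lowest state index wins.
* **Empty clusters**: re-seeded from the volume farthest (in correlation
  distance) from its current centroid.
* **Degenerate input**: volumes that are constant across parcels have no
  defined correlation and are rejected at validation with an explicit error;
  they do not occur after any reasonable confound regression, and silently
  imputing a distance would corrupt the objective.

### Occupancy and the high-occupancy summary

`FO[i, s]` is the fraction of participant `i`'s retained volumes assigned to
state `s`; rows sum to one by construction. States are ranked by *cohort
mean* occupancy (medians are reported alongside, and exact ties go to the
lower state index); the top two are the analysis states. The per-participant
summary `fo_high` is the arithmetic **mean** of the two top-state
occupancies. The mean (rather than the sum) keeps `fo_high` on the scale of a
single state's occupancy (~0.25 in a five-state solution), which matches the
intercept scale of the primary regression; a `method = "sum"` option is
exposed for sensitivity analyses but is not the default.

### Network profiles

Each state's centroid is split into its positive part $\max(c, 0)$ and
negative part $\max(-c, 0)$, and each part is compared with the binary
parcel-membership indicator of the seven canonical large-scale networks by
cosine similarity. All-zero parts get similarity 0 by convention. In the
generator's ground truth the two high-occupancy states are DMN activation
(DMN+) and DMN suppression (DMN−), which the profile recovers.

## 2. Regression models

### Fixed-dispersion beta regression (primary)

The occupancy summary is a proportion, modelled as

$$y_i \sim \mathrm{Beta}(\mu_i \phi,\ (1 - \mu_i)\phi), \qquad
  \operatorname{logit}(\mu_i) = x_i^\top \beta,$$

with one precision $\phi$ shared by all observations. Estimation is full
maximum likelihood over $(\beta, \log\phi)$ — the log keeps $\phi$ positive —
by BFGS with analytic gradients followed by Newton polishing of the score;
starting values are a least-squares fit on the logit scale and a
moment-matched $\phi$. The Newton stage stops when the maximum absolute score
falls below `max(1e-8, 1e-7 * (1 + |logLik|))`: below that level the
objective is flat to machine precision, so a tighter absolute criterion would
be noise-chasing. Wald standard errors come from the inverse observed
information of the full parameter; confidence intervals are Wald at
$\alpha = 0.05$, matching the reporting style of the downstream tables (no
profile-likelihood intervals).

Responses exactly at 0 or 1 are a hard error by default, with an opt-in
shrinkage `(y (n - 1) + 0.5) / n` (`shrink_boundary = TRUE`) that is never
applied silently. In very small or very noisy clustered samples a participant
can receive zero volumes in both top states; pipeline wrappers thread the
option through so such runs fail loudly unless the analyst opts in.

### WMH covariate transform

Non-zero WMH volumes enter as natural logarithms; exact zeros keep the value
0 and raise a binary indicator `1{WMH = 0}`. The indicator is included in a
model exactly when zeros and non-zeros coexist in the analyzed sample — if
all volumes are positive the column is constant, hence collinear with the
intercept, and is dropped; the remaining estimates are unchanged by this rule
(tested). Effects on log-WMH are reported as the odds ratio per
*interquartile ratio* `Q3/Q1` of the analyzed sample's non-zero volumes:
$\mathrm{OR} = \exp\{\hat\beta_{\log \mathrm{WMH}} \cdot \log(Q3/Q1)\}$, with
CI endpoints transformed identically. Monotone reporting transforms never
alter p-values.

### Gamma and binomial GLMs (secondary and exploratory)

TMT-B completion times are strictly positive and right-skewed; they are
modelled by a Gamma GLM with log link fitted by IRLS (`stats::glm` with the
deviance tolerance tightened to `1e-12` so estimates agree with an
independent maximizer of the Gamma likelihood to `1e-6`), Pearson-based
dispersion, and Wald inference. The occupancy effect is reported per 5
percentage points, $\exp(\hat\beta_{\mathrm{FO}} \cdot 0.05)$, since
occupancy enters the model in proportion units (5 pp = 0.05 on that scale);
age is entered in years and reported per 10 years by the
same scaling device. Bounded cognitive scores (e.g. 0-30 screening
instruments) use a logit-link binomial GLM with odds ratios reported per 20
(or 5) percentage points; separation is detected (non-convergence or runaway
coefficients) and raised as an error naming the covariate.

## 3. WMH mask quantification

Binary segmentations are post-processed in two steps, in this order (the
filter precedes the partition):

1. **Cluster-size filter**: 26-connected components with fewer than 30 voxels
   are zeroed. Connectivity is not dictated by the upstream segmentation
   tools; 26-connectivity (face, edge and corner neighbours) is chosen and
   documented, and components are found by a vectorized union-find over
   foreground voxels.
2. **Periventricular/deep partition**: each remaining lesion voxel is
   classified by the exact Euclidean distance (in mm, anisotropic spacing
   honoured, voxel centre to voxel centre) to the nearest ventricle voxel:
   `<= 10 mm` periventricular, `> 10 mm` deep. The boundary case `= 10 mm`
   is assigned periventricular by convention. The partition is voxel-wise, so
   a single lesion may straddle both classes; periventricular + deep always
   equals the total volume (asserted to 1e-9 mL). Volumes are
   `voxel count x voxel volume / 1000` mL.

Distances are computed by blocked exact nearest-neighbour search rather than
a grid distance transform: it is exact for anisotropic spacing, trivially
verifiable against an all-pairs oracle, and fast at realistic mask sizes.

## 4. The synthetic-cohort generator

The generator produces cohorts with the statistical structure the analysis
assumes, with known ground truth. Its defaults are the study conditions, set
once and analytically:

* **Demographics.** Age, sex, and education are drawn from quartile-matching
  piecewise-uniform histograms (age median 66, IQR 59-72; education median
  13) and a 57/43 male/female split. Only medians and IQRs are targeted —
  higher moments of the true population are not modelled.
* **WMH volume.** Zero with probability 9/1651 (~0.5%), otherwise log-normal
  with `meanlog = log(1.05)` and `sdlog = log(5.06) / (2 * qnorm(0.75))`
  (≈ 1.202), giving median 1.05 mL and interquartile ratio 5.06 exactly in
  the population. Log-normality is an assumption: the analysis pipeline
  log-transforms volumes and the reported quartiles are compatible with it,
  but the true distribution family of lesion volumes is not knowable from
  quartiles alone. A periventricular/deep split (Beta-distributed deep
  fraction with an extra zero mass) is loosely matched to the reported
  component medians.
* **Occupancy link.** Each participant's latent high-state occupancy is
  $\mathrm{FO}^{\mathrm{high}}_i \sim \mathrm{Beta}(\mu_i \phi_{\mathrm{gen}},
  (1 - \mu_i)\phi_{\mathrm{gen}})$ with
  $\operatorname{logit}(\mu_i) = b_0 + b_w \log \mathrm{WMH}^+_i + b_z
  1\{\mathrm{WMH}_i = 0\} + \text{covariate terms}$ and
  $b_w = \log(\mathrm{OR}_{\mathrm{IQR}}) / \log(Q3/Q1)$, default odds ratio
  0.95 per interquartile ratio. The intercept is centred so the cohort mean
  equals the occupancy target under the default covariate marginals.
  $\phi_{\mathrm{gen}} = 80$ is calibrated once so that the *realized*
  occupancy (latent Beta variance plus multinomial label noise at 100-125
  volumes) has an IQR near 20.8-28.0%, and fixed.
* **Labels.** Given $\mathrm{FO}^{\mathrm{high}}_i$ (the *mean* occupancy of
  the two high states), labels over the five states are i.i.d. with
  probability $\mathrm{FO}^{\mathrm{high}}_i$ for *each* high state and the
  remaining mass split over the three low states in proportion to their
  targets. Because the two high states are exchangeable under this law, their
  realized means are both the average of the two high-state targets; the
  slight DMN+/DMN− asymmetry of the observed medians is not representable
  and is not a generator target. The analyses use occupancy only, so label
  order within a scan is irrelevant; a temporal-persistence hook
  (`persistence` = $\rho$, Markov transitions
  $(1-\rho)\mathbf{1}\pi^\top + \rho I$, stationary law exactly $\pi_i$) is
  exposed for future dwell-time work and defaults to 0.
* **BOLD volumes.** Volume at time $t$ = planted centroid of its state label
  plus i.i.d. Gaussian parcel noise (amplitude 1, noise SD 0.5). State 1
  activates the default-network parcels, state 2 suppresses them, states 3-5
  activate other networks. Parcels carry seven network labels in contiguous
  blocks.
* **TMT-B.** $E[\mathrm{TMT}_i] = \exp\{c_0 + 20\log(m_5)\,
  \mathrm{FO}^{\mathrm{high}}_i + \text{nuisance}\}$ with default multiplier
  $m_5 = 0.98$ per 5 pp, Gamma-distributed with shape 8 (residual
  coefficient of variation ≈ 0.35, consistent with the reported TMT-B spread
  after covariate effects). The intercept is centred to a median near 83 s.

What the generator does **not** emulate: spatially autocorrelated BOLD noise,
scanner drift and physiological confounds, motion and its correlation with
disease, residual structure left by real confound regression, atlas
misregistration, or measurement error in covariates. Passing tests therefore
establish that the *estimators and pipeline logic* are correct under the
assumed data-generating process — not that the scientific conclusions
transfer to any real cohort.

## 5. Pipeline analyses

* **Quality check** (outcome-neutral): per participant, the difference
  between the mean occupancy of the two high states and the mean occupancy of
  the remaining three; reported as the cohort mean with a normal-theory 95%
  CI. Under generator defaults the separation is ~7.7 pp by construction
  (the symmetrized occupancy targets imply 0.246 − 0.169), and the CI
  excludes zero.
* **Multiverse grid**: 9 named confound-regression variants x 9 parcellations
  (86-400 parcels) x 3 WMH components = 243 scenarios, or 81 when restricted
  to total volume. The variants are *labeled perturbations of the generator
  and post-processing* — noise scaling, volume censoring emulating
  scrubbing/spike removal, a shared global component for strategies without
  global-signal regression — not re-implementations of the original
  de-noising software; the grid exercises the executor and the robustness
  summary (counts of nominally significant negative/positive cells, no
  multiplicity correction, failures recorded per cell rather than fatal).
* **Bootstrap power curve**: resamples of each target size are drawn with
  replacement from a reference cohort; the power at size `n` is the fraction
  of resamples rejecting the primary null at `alpha`. Each (size, replicate)
  pair runs on a child seed of the master seed, so curves are reproducible
  and order-independent. Note that bootstrap power estimates the power
  against the *empirical* effect of the reference sample: under a null
  generator it approaches `alpha` only when the reference cohort is large
  enough that its own chance association is negligible, which is how the
  null-calibration checks are set up. Degenerate resamples (all-identical
  WMH) are recorded as non-rejections with a warning.

## 6. Problem sizes and verification strategy

Estimator-level checks run at the size where their guarantees are sharp:
exhaustive k-means enumeration on 4-8 volumes, optimizer agreement on 50-70
observation fits to 1e-6, beta-regression recovery at n = 10^4. Cohort-level
checks (CI coverage across 100 replicates at n = 1500, type-I error over 2000
null cohorts, null bootstrap power against an n = 8000 reference) use the
generator's multinomial fast path — label counts rather than label sequences
and BOLD — because occupancy is a deterministic function of the counts;
clustering-based recovery (planted-label agreement above 90%, occupancy
medians near 24-25%) is verified separately on reduced cohorts (tens of
participants, 40-100 parcels), and the 243-cell multiverse runs at ~30
participants per cell. These sizes are the package's own verification
choices: each check is placed at the smallest scale at which it is
informative.

## 7. Known limitations

* **Attenuation in the secondary model.** The TMT-B outcome is generated from
  the *latent* occupancy, while the fitted model uses the *realized*
  occupancy, which carries multinomial measurement noise at 100-125 volumes
  per scan. Classical errors-in-covariates attenuation shrinks the recovered
  per-5-pp multiplier from 0.980 toward ~0.984 (reliability ≈ 0.80 at the
  default dispersion). The same phenomenon affects any occupancy-as-covariate
  analysis of real scans of this length; the acceptance checks verify that
  Wald CIs nonetheless cover the generative truth in ≥ 90% of cohorts.
* **Beta likelihood is quasi-true.** Realized occupancy is a Beta-multinomial
  mixture, not exactly Beta; the logit-mean model remains correctly specified
  for the conditional mean, and the type-I error of the Wald test is verified
  at 0.05 ± 0.01, but the fitted `phi` reflects total (latent + counting)
  variance, not the latent precision.
* **Occupancy only.** Dwell times, transition statistics, and HMM-style
  state models are out of scope; the persistence hook only future-proofs the
  generator.
* **Cosine profiles are descriptive.** Network similarity uses binary parcel
  indicators and is not a statistical test of network involvement.
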