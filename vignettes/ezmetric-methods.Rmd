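---
title: "Methods: weighted embryonic-zebrafish toxicity scoring and modelling"
author: "ezmetric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted embryonic-zebrafish toxicity scoring and modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezmetric)
```

This vignette documents the statistical procedures implemented in
`ezmetric`, the assumptions behind them, the choices we made where more than
one defensible convention exists, and what the synthetic-data validation
does and does not demonstrate about real screening data.

## The assay and the weighted score

Embryonic zebrafish are exposed individually in 96-well plates from 8 hours
post fertilization (hpf), across a fivefold serial dilution series
(typically 250 ppm down to ~16 ppb) plus a fishwater control. Each embryo is
scored for viability at 24 and 120 hpf and for 19 binary sub-lethal
endpoints — early development (developmental delay, 24-hpf notochord
malformation, spontaneous movement), 120-hpf morphology (heart, brain, yolk
sac, axis, trunk, eye, snout, jaw, otic vesicle, somite, fin, circulation,
pigmentation, swim bladder) and behaviour (motility, touch response).

Each endpoint carries a severity weight in [0, 1] (`ez_weights()`):
mortality at 24 hpf weighs 1.0, mortality by 120 hpf 0.95, and the 19
sub-lethal weights range from 0.12 (heart, brain) to 0.02 and sum to 0.94.
The ordering encodes a consensus severity ranking; the 0.94 < 0.95
relationship guarantees that converting any surviving embryo — however
malformed — into a death can never lower the group score (tested as the
mortality-dominance property).

For one material at one concentration the group score is

$$\mathrm{EZ} \;=\; w_{24}\,f_{24} \;+\; w_{120}\,f_{120}
 \;+\; \frac{1}{n}\sum_i w_i\,c_i ,$$

with $f_{24}, f_{120}$ the mortality fractions and $c_i$ the count of viable
embryos showing endpoint $i$ among the $n$ exposed.

**Normalization choice.** "Frequency normalized by viable embryos" admits
two readings: dividing the sub-lethal counts by the viable count alone (a
score that can exceed 1 when mortality and malformations co-occur), or
additionally scaling by the surviving fraction. We adopt the scaled form,
which is algebraically identical to the mean over embryos of a per-embryo
severity (1.0 if dead at 24 hpf, 0.95 if dead by 120 hpf, otherwise the sum
of the weights of its observed endpoints). It is bounded in [0, 1], makes
EZ = 0.5 interpretable as a 50 % integrated effect — the reading the EC50
relies on — and is verified against an independent per-embryo oracle on
randomized groups. The unscaled variant remains available through
`weighted_ez_score(..., scale_survival = FALSE)` for sensitivity analysis.

Two further conventions: embryos that die between 24 and 120 hpf contribute
only the 0.95 mortality weight — any 24-hpf observations on them are
discarded, since the mortality weight already dominates the full sub-lethal
sum; and groups with zero viable embryos contribute only mortality terms (no
0/0). Records that flag sub-lethal endpoints on embryos dead at 24 hpf are
rejected at validation rather than silently zeroed, to surface upstream data
errors.

**sumEZ.** A material's summed score over its treatment concentrations. The
dilution design is ambiguous about whether the control belongs in the sum
(a 7-step fivefold series from 250 ppm ends at 16 ppb, while the summary is
conventionally taken over 8 values); we store the 0-ppm control in the
profile but exclude it from sumEZ and from EC interpolation (its log
concentration is undefined), and the generator's default of 8 treatment
dilutions reconciles the two readings. `n_dilutions = 7` reproduces the
7-step design exactly.

## Effect concentrations

Many materials do not produce a 50 % effect at the highest tested dose,
which rules out logistic or sigmoidal model fits as a general tool here.
`estimate_ec()` therefore scans adjacent treatment points in ascending
concentration and linearly interpolates the target score on the log10
concentration axis at the first pair whose scores straddle it from below.
No extrapolation is performed:

* lowest treatment score already at or above the target → status
  `below_range`, the lowest tested concentration is reported as a
  conservative bound;
* no crossing anywhere → status `not_reached`, value `NA`.

First-crossing-from-below is the tie-break for non-monotone profiles
(sampling noise at 12 embryos per group makes mild non-monotonicity common);
an isotonic pre-smoothing was considered and rejected as a default because
it changes reached/not-reached status in edge cases and the plain rule is
what the interpolation method states. Scale equivariance (multiplying all
concentrations by k multiplies a reached estimate by k) and convergence to
the true ECx of densely sampled logistic curves are enforced by tests.

Hazard ranking sorts materials with a usable EC50 first (ascending), then
materials with only the fallback EC at score 0.1, then the rest;
lexicographic id order breaks ties deterministically.

**Spearman correlations.** `spearman_rank()` computes the Pearson
correlation of mid-ranks with a t-approximation p-value on n − 2 degrees of
freedom. Correlating EC50s with *categorical* material attributes requires a
numeric encoding of the categories; because the result depends materially on
that encoding and no canonical one exists, the encoding is left to the
caller and no particular published coefficient is treated as reproducible.

## Profile clustering and classification

Profiles are aligned on a common concentration grid (`profile_matrix()`,
with `error`, `zero` or log-linear `interpolate` fill policies) and
clustered by agglomerative Ward linkage on Euclidean distances.

**Height convention.** Dendrogram software disagrees on Ward height
conventions (raw merge cost, doubled cost, square roots). We report the
merge cost itself — the increase in total within-cluster sum of squares
caused by the merge — computed by the Lance–Williams recurrence seeded with
half the squared Euclidean distance for singleton pairs. Heights are
verified against a brute-force oracle that recomputes every candidate
merge's SSE increase directly, and against the doubled-height convention of
the standard ward.D linkage on squared distances. Cost ties (possible with
duplicated profiles) resolve to the smallest pair of active indices, making
the result deterministic; the two-cluster cut used downstream is independent
of the height convention.

The two top-level subtrees become clusters A and B, with **B** assigned to
the larger mean sumEZ — i.e., the label "B" operationally means "the more
toxic cluster". Per-cluster sumEZ summaries (min, quartiles, mean, max) are
returned for box-plot-style comparison.

**Classification.** Cluster membership is predicted from four binary
surface-group features (TMAT, phosphate, phosphatidylcholine, amine) with a
greedy gain-ratio decision tree: information gain divided by split
information, split accepted only when the gain is positive, majority leaf
(tie → A) otherwise. With four binary features and two classes the
hypothesis space is tiny and pessimistic pruning has nothing to prune, so no
pruning is implemented — a deliberate simplification relative to full C4.5.
Both leave-one-out (deterministic, seed-free) and stratified ten-fold
cross-validation are provided, since both schemes are standard for panels of
this size; leave-one-out is the default for exact reproducibility. A fold
whose training split contains one class yields a majority-leaf tree rather
than an error.

## The response-surface model

For a panel of surface-modified gold nanoparticles the modified score
`mod = 100·EZ + 0.1` (the 0.1 offset avoids the log-of-zero discontinuity;
`mod_transform()` / `mod_inverse()`) is modelled as

$$\mathrm{mod} = \exp\big(\beta_0 + \beta_1 \ln C + \beta_2 S
 + \beta_3 \tfrac{\mathrm{SASA}}{\mathrm{Polar}} + \beta_4 \mathrm{Refr}
 + \beta_5 \mathrm{Gap} + \beta_{13} \ln C\cdot\tfrac{\mathrm{SASA}}{\mathrm{Polar}}
 + \beta_{25} S\cdot\mathrm{Gap} + \beta_{11} (\ln C)^2 + \beta_{22} S^2\big)$$

with $C$ the concentration in ppm (natural logarithm; the unit choice
inside the log shifts only the intercept), $S$ the primary particle diameter
in nm, and the three ligand descriptors (SASA/polar-surface ratio, molar
refractivity, HOMO–LUMO band gap) taken from the packaged table for MEE,
MEEE, TMAT and MES thiols. Descriptors that did not improve predictive
ability in the source analyses (logD/logP, polarizability, van der Waals
surface area) are excluded from the design. The coefficient subscripts are
labels, not semantics.

**Fitting.** Unweighted nonlinear least squares on the mod scale by
Levenberg–Marquardt with the analytic Jacobian $J = e^{X\beta}\,X$,
initialized at the OLS fit of $\ln(\mathrm{mod})$ on the design matrix.
Because noise-free model data are exactly log-linear, that start is already
the optimum and the fitter terminates immediately (asserted in tests, along
with exact recovery of the generating coefficients). Numerical choices:

* the damped step is solved through the QR factorization of the augmented
  Jacobian rather than the normal equations — fitted values here span many
  orders of magnitude and squaring the condition number of $J$ destroys the
  small-singular-value directions;
* convergence at relative SSE change < 1e-10 (500-iteration cap), plus an
  absolute floor of $\varepsilon^{3/2}\sum y^2$ that recognizes
  machine-precision-perfect fits;
* hitting the iteration cap returns the best fit found with a warning (the
  convention of standard NLS tools), reserving hard errors for non-finite
  objectives and rank-deficient designs (reported with the collinear columns
  named);
* the linear predictor is clipped at 700 before exponentiation, with a
  warning, to guard overflow.

Standard errors come from $s^2 (J^\top J)^{-1}$ at the optimum (computed via
QR), p-values from the t distribution with $n - 10$ degrees of freedom.
$R^2$ is reported on the mod scale ($1 - \mathrm{SSE}/\mathrm{SST}$) with a
log-scale $R^2$ alongside, since the scale on which fit quality is judged is
itself a modelling choice.

**Outlier screening.** Observations with externally studentized residuals
beyond a configurable threshold (default |t| > 3) are flagged;
`remove_outliers = TRUE` drops them once and refits, mirroring a
remove-then-refit diagnostic flow. Two caveats are documented from
experiments with synthetic contamination: a perfect (machine-precision) fit
yields no outliers by definition; and *extreme* contamination (a response
inflated by ~10⁶) distorts the non-robust LS fit enough to drag clean
observations past the threshold (swamping) — the contaminant is still
flagged and a refit recovers the generating surface, but the flagged set is
a superset. Moderate contamination (up to ~10³) is flagged exactly.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is validated.

* **Plates** (`simulate_plate()`): 12 embryos per group (real replicate
  structures are unpublished; 12 matches one plate row per concentration),
  eight fivefold dilutions from 250 ppm plus a clean control (background
  rate 0 by default, configurable). Every endpoint follows a Hill curve
  $H(c) = c^h/(\mathrm{ed50}^h + c^h)$; death by 24 hpf, then death by
  120 hpf among survivors, then independent sub-lethal endpoints among
  viable embryos. The baseline (mortality ed50 80/40 ppm, sub-lethal ed50s
  25–120 ppm with severity roughly tracking sensitivity, slope 2) describes
  a moderately toxic material with an EC50 of a few tens of ppm. A
  material's potency divides every ed50.
* **Panels** (`simulate_panel()`): 68 materials; each carries one of the
  four toxicity-associated surface groups with probability 0.5; carriers
  get potency 20 (effective mortality ed50 ~4 ppm — strongly toxic),
  non-carriers 0.02 (inert in range). This two-stratum design emulates the
  empirical pattern that carriers of these groups cluster together as the
  high-toxicity group; `label_noise` decouples a fraction of materials from
  their stratum to emulate real-panel misfits.
* **Model observations** (`simulate_model_observations()`): inverts the
  exponential surface over a ligand × size × concentration grid, adds
  optional Gaussian noise on the mod scale, floored at 0.1.

**What passing tests show — and don't.** The generator's independence
assumptions (endpoints independent given dose; embryos independent) are the
simplest structure exercising every pipeline stage; real malformations
co-occur within embryos, real plates have batch effects, and real potency is
not a single multiplier. Recovery of the planted two-cluster structure
(adjusted Rand ≥ 0.9) and perfect leave-one-out accuracy on noiseless
rule-consistent labels therefore validate the *algorithms*, not the
biological claim; the original panel cannot be reconstructed without the
source database, and no attempt is made to reproduce its numeric EC50 table.

**Validation problem sizes.** The suite checks the per-embryo oracle on
1,000 randomized groups; Ward merges against brute force for all random
matrices with n ≤ 6; frequency convergence at 10⁴ embryos per group
(tolerance 0.02 absolute); and standard-error calibration over 200 noisy
refits of the 128-cell model grid. For the coverage run the noise is set to
σ = 2 on the mod scale: there the Wald linearization is calibrated (joint
3-SE coverage ≈ 0.96, per-interval ≈ 0.99 in our measurements). At
substantially larger noise (σ ≈ 5) the second-order curvature of the
exponential model biases several coefficients by about one standard error
and 3-SE coverage degrades to ≈ 0.9 — a known limitation of Wald intervals
for strongly nonlinear models, worth remembering when interpreting reported
standard errors on noisy data.

## Known limitations

* EC estimates inherit the step resolution of the dilution series; a
  fivefold series bounds the log10 interpolation error accordingly.
* The score treats endpoint weights as fixed constants; no uncertainty in
  the weighting is propagated.
* The gain-ratio tree is unpruned and restricted to the four binary surface
  groups; panels with richer feature sets would need pruning or ensembles.
* The response-surface model extrapolates explosively outside the fitted
  size/concentration envelope (it is exponential in quadratics); prediction
  surfaces should be read only over tested ranges.
* Spearman correlations with categorical attributes depend on the caller's
  encoding, and are deliberately not tied to any reference value.
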