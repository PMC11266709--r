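---
title: "Methods: staged elastic-net discovery of prognostic and prescriptive predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged elastic-net discovery of prognostic and prescriptive predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(moderanet)
```

## The modeling problem

A two-arm randomized trial (active treatment vs monitored control, 30
participants per arm) measures baseline demographics, depression severity
(PHQ-9, 0–27), six conflict-task behavioral scores and six resting-state
connectivity edges, and a post-treatment severity outcome. The scientific
question is which baseline variables predict the outcome — and, through
treatment-group interactions, which predict it *differentially* under
active treatment (prescriptive or moderator effects). With n = 60 and ~19
design columns per stage, single-fit inference is fragile; the pipeline
instead characterizes each variable by the *stability* of its selection
under repeated cross-validated penalty tuning.

## Behavioral scoring

From each participant's trial log (five blocks of 70 trials, 46 congruent
and 24 incongruent per block) six scores are computed:

* **Interference** — accuracy: `mean acc(congruent) − mean acc(incongruent)`;
  RT: `mean RT(incongruent, correct) − mean RT(congruent, correct)`.
  Oriented so higher = worse inhibitory control.
* **Congruency-sequence (Gratton)** — among incongruent trials whose
  *previous* trial (same block, and answered correctly) was incongruent
  (iI) vs congruent (cI): accuracy `iI − cI`, RT `cI − iI`. Higher =
  better sustained attention. Requiring a correct predecessor keeps this
  contrast from absorbing post-error adjustments; pairs never span block
  boundaries, so the first trial of a block contributes only as a
  predecessor.
* **Post-error adjustments** — trials immediately following an error vs
  following a correct response: RT slowing (Rabbitt) and accuracy change
  (Laming), each `post-error − post-correct`, current-trial congruency
  unconstrained.

RT summaries use correct trials only and plain means (no trimming) — the
standard conflict-task conventions; both choices are configurable at the
scoring call. Quality control flags a score family missing when any
contributing cell holds fewer than 5 trials (interference additionally
when overall accuracy drops below 0.5, i.e. chance responding); QC
produces missingness for the imputation step, never errors.

## Connectivity features

ROI time courses (dACC, left AI, right AI, right TPJ) are correlated
pairwise (Pearson, columns mean-centered; the n−1 vs n denominator cancels
in r), Fisher-z transformed (`z = atanh(r)`, variance-stabilizing, SE
≈ 1/sqrt(T−3)), and flattened to six canonically ordered edges. Upstream
fMRI preprocessing is out of scope: input begins at the time-series level,
and a precomputed edge table is equally acceptable.

## Iterative forest imputation

Missing baseline entries are imputed by the iterative random-forest
scheme: initialize with column means/modes, then repeatedly re-fit a
forest per incomplete column (visiting columns in ascending missingness)
and re-predict its missing cells, stopping the first time the normalized
change statistic increases (computed separately for continuous and
categorical columns) and returning the previous iteration; otherwise at
`max_iter = 10`. Forests use 100 trees. Observed cells are never altered.
The post-treatment outcome is excluded from the predictor set by default
so that imputing baseline variables cannot leak outcome information — a
conservative choice, configurable via `exclude`.

## The elastic net and its tuning

For standardized outcome `y` and design `X` (standardized numeric mains;
0/1 indicators for group and gender left unscaled; interaction columns as
exact products of the group indicator with the standardized covariate,
*not* re-standardized, which preserves their "additional effect within the
treated arm" reading), the solver minimizes

$$\frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2
  + \lambda\Big(\alpha\lVert\beta\rVert_1
  + \tfrac{1-\alpha}{2}\lVert\beta\rVert^2\Big)$$

by cyclic coordinate descent with soft-thresholding, the intercept
unpenalized. Numerical choices: columns and outcome are centered so the
intercept drops out; the Gram quantities are precomputed, and a gradient
residual is maintained incrementally so warm-started paths are cheap;
convergence requires the largest coefficient change in a sweep to fall
below 1e-7; the per-sweep objective is recorded and is non-increasing.
At `lambda = 0` the solution agrees with ordinary least squares; at
`lambda >= lambda_max = max_j |x_j'y|/(n alpha)` all coefficients are
exactly zero (for `alpha = 0` a conventional floor of 0.001 supplies a
finite path start).

Tuning searches `alpha` over `{0, 0.1, ..., 1}` crossed with a per-alpha
geometric path of 100 lambdas from `lambda_max` down to
`0.001 lambda_max`, scoring each pair by 10-fold cross-validated MSE under
a random fold partition, and returns the minimizing pair (minimum-MSE
rule; no 1-SE rule). Exact ties — routine at the all-zero top of the paths
— resolve to the larger lambda, then the larger alpha.

## Replicated selection and the three stages

A *replicate* redraws the CV folds, re-tunes `(alpha, lambda)`, and refits
on the full sample; the data are never resampled, so replicate-to-replicate
variability isolates the fold-randomization sensitivity of penalty
selection. Per design column the pipeline reports the proportion of
replicates with a nonzero coefficient (`pi`) and the mean coefficient with
zeros included (median optional). A column is **retained** when
`pi >= 0.75` (inclusive) and **essential** when its |mean coefficient|
strictly exceeds the average over retained columns — with the corollary
that a single retained column, or all-equal magnitudes, yields an empty
essential set.

Stage 1 screens `{age, gender, baseline severity}` plus the six behavioral
scores; Stage 2 swaps in the six edges; Stage 3 enters baseline severity
plus every covariate whose main effect *or* interaction was retained
earlier (the group indicator and all interactions are present at every
stage). At study scale the replicate count is 10,000; the test suite and
acceptance script use 500 (sampling error of `pi` at most ~0.022) and the
null-calibration study 100–200 per dataset — sizes chosen to keep the full
suite re-runnable on one CPU in minutes while leaving the binomial noise
on `pi` an order of magnitude below the decisions it feeds.

## Model evaluation and the corrected t-test

Prediction error is estimated by nested cross-validation: each run draws
an outer 10-fold partition; on each outer training set every stage model
is re-tuned (inner 10-fold) and refit, then scored on the held-out fold;
the null model predicts the outer-training-set mean (on the standardized
outcome its MSE sits near 1). Per-run mean MSEs are compared by the
variance-corrected resampled t-test,

$$t = \bar m \Big/ \sqrt{\Big(\tfrac1J + \tfrac{n_{test}}{n_{train}}\Big) s^2},
\qquad df = J - 1,$$

which inflates the paired-t variance by the train/test overlap ratio (1/9
for 10-fold); with ratio 0 it reduces exactly to the classic paired t,
available behind `correction = "none"`. The five standard contrasts are
each stage vs null and Stage 3 vs Stages 1–2.

The essential Stage 3 predictors then enter an unpenalized OLS for
interpretation: R², the overall F-test (a 17-predictor fit on n = 60
reports F on (17, 42) df), coefficient plots, and adjusted-effect curves —
predictions over a focal variable's range with other covariates at their
means and the group indicator fixed per stratum, banded by ±1 SE of the
fit; at the focal mean each curve passes through the stratum's mean
prediction. Group-wise descriptives use adjusted (sample-size-corrected)
skewness and excess kurtosis, pooled-variance t-tests (df 58 for 30/30
arms) and a df-1 chi-squared for gender without continuity correction
(Yates optional) — the conventions of psychology reporting.

## The synthetic cohort: what it emulates, and what it does not

The generator reproduces the study's *structure*: 30 participants per arm;
baseline severity uniform on 10–23; gender Bernoulli with P(F) = 38/60;
age ~ N(29.6, 7.4²); five 70-trial blocks in randomized within-block
order; per-participant condition accuracies and lognormal RTs (right-
skewed, strictly positive; `rt_sigma = 0` degenerates to the exact
condition means, which the scoring tests exploit) with additive
sequential-dependency shifts so Gratton and post-error effects are
plantable — defaults give group-level effect sizes near those typical of
depressed samples (accuracy interference ≈ 0.21, RT interference ≈ 88 ms,
Gratton-accuracy d ≈ 0.75, post-error-RT d ≈ 0.36, null Gratton-RT and
post-error-accuracy effects). ROI series are Gaussian with population
correlations set to pooled literature-typical Fisher-z values
back-transformed with tanh; 200 timepoints by default (a typical
resting-state scan length), with per-participant jitter of SD 0.18 on the
z scale, shrunk toward the base matrix whenever the jittered matrix loses
positive semi-definiteness.

Outcomes follow a linear model on internally standardized features —
prognostic weights, group-interaction weights, a treated-arm main effect
(−0.73 SD) and Gaussian noise (SD 1) — then an affine display map to
severity units (mean 10.6, SD 4.8); the modeling pipeline standardizes the
outcome, so the display map never influences selection or evaluation.
Default planted directions: worse (slower) Flanker RT predicts higher
post-treatment severity, more strongly in the treated arm; weaker right
AI–left AI and stronger right AI–TPJ connectivity predict higher severity,
again more strongly under treatment; the Gratton-accuracy effect is
protective and the post-error-accuracy effect harmful in the treated arm
only; baseline severity is prognostic. Missingness is completely at
random: a participant's scan is lost with probability 0.15 (all six edges
jointly), and Gratton/post-error scores are masked so that the *total*
numbers of participants with missing scores are 7 and 12.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: fMRI acquisition artifacts, motion and
physiological noise (series arrive "denoised"); item-level severity
structure (scale totals only, continuous rather than integer);
informative (non-MCAR) missingness; distributional quirks of real RT data
beyond lognormality; and criterion-based QC (the 7/12 QC failures are
count-matched, not derived from behavioral criteria, which the study did
not publish).

## Behavior under the null, and other known limitations

On cohorts with **no** planted effects, minimum-MSE tuning over an alpha
grid that includes ridge (`alpha = 0`) is not calibrated as a selector: for
a sizeable fraction of null datasets the cross-validated surface favors a
dense solution — ridge coefficients are never exactly zero — for
essentially every fold randomization, so every column's nonzero proportion
reaches 1 and the retention rule admits noise variables wholesale. This is
a property of the procedure, not of this implementation: `cv.glmnet`
tuned over the same grid on the same imputed null datasets selects
`alpha = 0` in 100% of replicates on such datasets and "retains" all 19
columns identically. The acceptance suite asserts the nominal calibration
bounds and deliberately leaves them red rather than patching the procedure
(e.g. with a 1-SE rule, an alpha floor, or a coefficient-magnitude screen)
into something it is not. In the presence of real signal the surface is
far better behaved — planted effects are retained with `pi ≈ 1` while
typical noise columns stay below threshold — which is the regime the
procedure is used in.

Other limitations worth naming: replicate variability reflects fold
randomization only (no bootstrap, so `pi` says nothing about sampling
variability of the cohort itself); penalized coefficient summaries are
shrunken and not directly comparable to OLS effects; the corrected t-test
is approximate, and with per-run aggregation its printed df understates
the information actually shared across runs; and single imputation
propagates no imputation uncertainty into downstream inference.
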