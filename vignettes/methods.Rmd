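---
title: "Two-stage Super Learning for continuous-treatment dose-response curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Super Learning for continuous-treatment dose-response curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsdr)
```

## The estimand and its identification

For a continuous treatment $T \in [t_0, t_1]$ with potential outcomes
$Y(t)$, the targets are the average dose–response function
$\mu(t) = E[Y(t)]$ and the marginal treatment effect function
$(\mu(t) - \mu(t-\Delta t))/\Delta t$. Identification rests on three
assumptions: *weak unconfoundedness* ($Y(t) \perp T \mid X$ for every $t$),
*consistency* ($T = t \Rightarrow Y = Y(t)$), and *positivity* (the
conditional treatment density $r(t, x) = f_{T|X}(t \mid x)$ is positive
where it is evaluated). Two identification routes are implemented:

* **Regression adjustment.** $\mu(t) = E[Q(t, X)]$ with
  $Q(t, x) = E[Y \mid T = t, X = x]$; the estimator predicts every unit's
  outcome at $T = t$ and averages.
* **Generalised propensity score (GPS) adjustment.** The scalar score
  $R = r(T, X)$ has the balancing property: within strata of $r(t, X)$,
  receipt of level $t$ is independent of covariates. Consequently
  $\mu(t) = E[\beta(t, r(t, X))]$ with
  $\beta(t, r) = E[Y \mid T = t, R = r]$, and the estimator averages
  $\hat\beta(t, \hat R_t)$ over units, where $\hat R_{t,i} = \hat r(t, x_i)$
  is the *counterfactual* score.

Both routes require a correctly specified model — the outcome regression
for the first, both the treatment density and the score-outcome regression
for the second. Rather than committing to one parametric form, each model
is estimated by a Super Learner.

## The two Super Learners

Given candidates $\hat f_1, \dots, \hat f_K$ and $V$-fold cross-validation
(default $V = 10$), the Super Learner selects the convex combination
$\hat f_\alpha = \sum_j \alpha_j \hat f_j$, $\alpha_j \ge 0$,
$\sum_j \alpha_j = 1$, minimising the cross-validated risk
$$ L(\hat f_\alpha) \;=\; \frac{1}{V} \sum_{v=1}^{V} \frac{1}{n_v}
   \sum_{i \in S_v} \ell\!\left(y_i, \textstyle\sum_j \alpha_j
   \hat f_{j, \bar v}(w_i)\right), $$
with $\hat f_{j,\bar v}$ trained on the sample excluding fold $v$. The
loss $\ell$ is the squared error for the outcome stage and the negative
log-likelihood $-\log \hat r_{j, \bar v}(t_i, x_i)$ for the density stage.
Note the risk is the *average of fold means*: with unequal fold sizes this
differs from the pooled mean, and the fold-mean form is the one
implemented. After the weights are solved, every candidate is refit on the
full sample and the weighted combination is used for all predictions and
density evaluations (counterfactual scores come from full-sample refits,
matching common two-stage practice).

### Candidate libraries

The defaults mirror a conventional applied specification ladder. For the
treatment density: normal-identity and gamma-log GLMs (the gamma capturing
right skew), each in four versions — main effects; plus squares of three
continuous covariates; plus pairwise interactions; plus both. For the
outcome: main-terms GLM, treatment-by-covariate interactions, two
quadratic-interaction forms, a quartic polynomial in treatment, additive
natural-spline models with 2 and 3 degrees of freedom per continuous
variable, and a shrinkage GLM. In GPS mode the same ladder is built on
$(A, r)$; the quadratic-in-both candidate contains the classical
parametric two-stage model
$\alpha_0 + \alpha_1 t + \alpha_2 t^2 + \alpha_3 r + \alpha_4 r^2 +
\alpha_5 rt$ (also available directly as `hi_quadratic()`). Binary
outcomes use binomial-logit candidates throughout; positive cost-like
outcomes use gamma-log plus a normal-identity main-terms model. Smooth and
shrinkage candidates for cost outcomes are normal-identity. Tree or
boosting learners are deliberately out of scope.

### Numerical choices in the engine

* **IRLS**: relative deviance tolerance $10^{-8}$, at most 100 iterations
  (`stats::glm.fit`). Non-convergence, rank deficiency, or genuine
  separation (boundary fitted probabilities *with* diverged standardized
  coefficients) raise a fit error; during cross-validation such a candidate
  is dropped with a warning and the ensemble proceeds with $K-1$.
* **Dispersions**: the normal variance is the maximum-likelihood mean
  squared residual ($1/n$), keeping the density loss coherent with ML
  scaling; the gamma dispersion is the Pearson chi-square estimator. The
  implied densities are Gaussian (mean $\hat\mu(x)$, variance
  $\hat\sigma^2$) and gamma (shape $1/\hat\phi$, scale
  $\hat\mu(x)\hat\phi$); the gamma density is 0 at $t \le 0$.
* **Design expansion**: continuous variables (more than two distinct
  training values) are centered at training means before powers and
  products, reducing collinearity without changing predictions; smooths
  are natural cubic spline bases with knots at training quantiles; binary
  covariates always enter linearly. Centering constants and knots are
  frozen in a schema so prediction reproduces the training expansion
  exactly.
* **Shrinkage candidate**: a ridge-penalized IRLS with a Gaussian prior of
  fixed scale 2.5 on standardized non-intercept coefficients (intercept
  free). It always produces finite coefficients, including under
  separation, and strictly shrinks the coefficient norm relative to the
  unpenalized fit.
* **Weight optimization**: both losses are convex in $\alpha$; the solver
  is an accelerated projected-gradient method (monotone FISTA) with exact
  Euclidean projection onto the simplex, objective tolerance $10^{-10}$,
  with an analytic gradient
  $-\tfrac{1}{n}\sum_i p_{ij} / \sum_k \alpha_k p_{ik}$ for the density
  loss. Density evaluations are floored at $10^{-30}$ before logging so a
  single outlying unit cannot produce an infinite risk. If the solver ever
  ends above the best single candidate it falls back to that vertex (the
  discrete Super Learner) with a warning. When candidates are duplicated
  the weights are not identifiable; the solver's solution is returned
  unmodified since downstream predictions are unaffected.
* **Ensemble re-cross-validation** (`cv_risk_of_ensemble`): the convex
  combination is treated as a single learner — inside each training split
  the weights are re-solved on inner folds — giving the "convex Super
  Learner" row of the cross-validation report and supporting the
  convex-versus-discrete comparison.

## Inference

There is no convenient closed-form asymptotic distribution for the
two-stage ensemble estimator, so inference is by nonparametric bootstrap:
units are resampled with replacement, and *each replicate re-runs the fold
assignment, the GPS Super Learner, the outcome Super Learner and the curve
estimation*, so the intervals carry the uncertainty of score estimation
and model selection, not just of the final regression. Intervals are
percentile 2.5%/97.5% over successful replicates (replicates that fail to
fit are dropped; more than 10% failures is an error). Percentile intervals
were chosen over normal-approximation or BCa as the common default for
this estimator class; the lower bound is not forced below the point
estimate. Replicate seeds derive deterministically from the master seed
and replicate index, so runs are bit-reproducible and replicates are
order-independent. The default is $B = 1000$ replicates on the grid
$t = 1, \dots, 24$ hours with $\Delta t = 1$.

## Diagnostics

Balance is assessed by tertile blocking: the treatment is cut at its
33.3%/66.7% quantiles; for each tertile the covariate mean difference
(in-tertile versus rest) and pooled-variance two-sample $t$-statistic are
computed, unadjusted and then within five quantile blocks of the GPS
evaluated at the tertile's median treatment level, averaging the *signed*
block statistics weighted by block size. Blocks containing only one group
are excluded with weights renormalized. The pooled-variance form is the
default (Welch is available); with a single block the adjusted statistics
equal the unadjusted ones exactly. Whether block-wise $t$-statistics
should be averaged or recomputed on pooled blocks is ambiguous in the
blocking tradition; the weighted mean of block-wise statistics is
implemented. Common support uses the same tertile logic: the support
interval at each tertile is bounded by the larger group minimum and the
smaller group maximum of the scores, and the overall off-support share is
reported — but never trimmed automatically. A config option can floor
counterfactual scores at a user-chosen quantile for near-violations of
positivity; it is off by default, since off-support units are reported
rather than removed.

## The synthetic cohort generator

Because the motivating cohort (acute brain-injury patients transferred to
specialist centres within 24 h) is not public, the package generates
structurally similar data: $n = 488$ by default; age
$\sim N(40.33, 17.51^2)$ truncated to $[16, 100]$; glucose lognormal,
haemoglobin normal; four binary severity indicators with prevalences
0.379, 0.543, 0.463, 0.156; a baseline-risk score in $(0,1)$ built
logistically from the other covariates plus latent noise (calibrated to
mean 0.23, SD 0.17); a gamma-distributed treatment with log-mean linear in
covariates, rejection-sampled into $(0, 24]$ hours; ~20% binary mortality
(logistic) and a right-skewed positive cost (gamma-log, mean ≈ 27.5k).
Scenario names fix the treatment effect (`null`, `linear`, `nonmonotone`)
and the confounding strength (0, or 1 for the `confounded_*` variants,
which scale the covariate-to-treatment coefficients). True curves
`true_dose_response()` are computed by Monte-Carlo integration over a
fresh covariate sample ($10^5$ draws by default).

Two deliberate realism choices: truncating the treatment at 24 h makes the
normal and gamma candidate densities *mildly misspecified*, exercising the
ensemble exactly where it should help; and the generator's covariates are
mutually correlated only through the risk score, which is simpler than a
real cohort. Passing tests on these scenarios therefore demonstrates
correct mechanics and the expected bias reduction under known confounding,
not performance under every real-data pathology (heavy ties, informative
missingness — missing data are out of scope; the pipeline is
complete-case and reports dropped rows).

## Problem sizes used in the shipped checks

The package's acceptance checks run scaled-down versions of the full
study design, chosen once as the smallest sizes at which the properties
of interest are stable: parameter recovery uses 20 cohorts of $n = 1000$
with the full default libraries; balance attenuation uses 50 cohorts of
$n = 500$; the bootstrap null-calibration study uses 50 cohorts of
$n = 300$ with $B = 200$ replicates, $V = 5$, and two candidates per
stage — a reduced ensemble that keeps the two-family structure (one
normal, one gamma density candidate; a linear and a quadratic-interaction
outcome candidate) while keeping the 10,000 double-Super-Learner refits
tractable. The full-size defaults ($n = 488$ cohorts, $V = 10$,
$B = 1000$, eight-plus-eight candidate libraries) remain the package
defaults for analyses.

## Known limitations

* No kernel-weighting, inverse-probability-weighting, matching or
  propensity-function-stratification estimators; regression and two-stage
  GPS adjustment only.
* The GPS balancing diagnostic is descriptive; no formal balance test
  battery and no automatic trimming.
* Candidate libraries are GLM/GAM/shrinkage ladders; no tree ensembles.
* Curve values below the minimum observed treatment are extrapolations and
  are flagged with a warning rather than clipped.
* Weights are not identifiable when candidates coincide (predictions are
  unaffected).
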