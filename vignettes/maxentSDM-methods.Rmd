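---
title: "Methods: maximum-entropy habitat modelling and range-shift analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy habitat modelling and range-shift analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxentSDM)
```

## The model

`maxentSDM` fits a presence–background species distribution model of the
Maxent family. The landscape is the set of grid cells where environmental
data exist; the model assigns each cell $x$ a raw probability

$$p_\lambda(x) = \frac{e^{\sum_j \lambda_j f_j(x)}}{Z(\lambda)},
\qquad Z(\lambda) = \sum_{x'} e^{\sum_j \lambda_j f_j(x')},$$

the Gibbs (maximum-entropy) distribution whose feature expectations are
pulled toward the presence-sample means. The weights maximize the
L1-regularized gain

$$G(\lambda) = \frac{1}{m}\sum_{i=1}^{m} \sum_j \lambda_j f_j(x_i)
  \;-\; \ln Z(\lambda) + \ln N \;-\; \sum_j \beta_j^{\mathrm{eff}}\,|\lambda_j|,$$

where $m$ presences index into the $N$-cell landscape and the $+\ln N$
term anchors the uniform model at $G = 0$, so the gain is read directly
as nats of improvement over "the species could be anywhere". The
landscape is the deduplicated union of presence and background cells:
a cell sampled twice contributes once to $Z$.

Assumptions worth keeping in mind: presences are treated as an
independent sample proportional to occurrence rate (spatial thinning,
below, is what makes this defensible); background cells describe
available environment, not absences; and environmental layers are
error-free and aligned on one grid.

### Features

Five feature types transform each variable $v$ (first min/max-scaled to
$z \in [0,1]$ by its training bounds and clamped outside them):

* linear $z$, quadratic $z^2$, pairwise products $z_1 z_2$;
* hinge features at knot $k$: forward $\max(0, z - z_k)/(1 - z_k)$ and
  reverse $\max(0, z_k - z)/z_k$, knots at training quantiles
  (50 per variable by default);
* threshold (step) features $\mathbf{1}[z \ge z_k]$
  (20 knots per variable by default).

The admitted combinations are the six canonical feature classes `L`,
`LQ`, `H`, `LQH`, `LQHP`, `LQHPT`. The letter–meaning mapping follows
universal usage in the SDM tooling ecosystem: H = hinge, P = product,
T = threshold. Knots are stored in raw variable units, so a serialized
model re-projects onto any stack without refitting.

### Regularization

Each feature's penalty is
$\beta^{\mathrm{eff}} = \mathrm{RM}\cdot\beta(\mathrm{kind}, m)\cdot
\mathrm{sd}(f\mid\mathrm{background})/\sqrt{m}$. The base schedule
$\beta(\mathrm{kind}, m)$ is piecewise-linear in the presence count
between anchors — linear/quadratic/product: $(0,1.0), (10,1.0), (30,0.2),
(100,0.05)$; hinge: constant $0.5$; threshold: $(0,2.0), (100,1.0)$ —
constant beyond the end anchors. This is the standard Maxent default
schedule; the single user-facing dial is the regularization multiplier
RM, tuned over $0.5, 1.0, \ldots, 4.0$.

### Optimizer

Cyclic coordinate descent with an exact soft-threshold step on the local
quadratic model, verified against the exact objective with backtracking:
an update is accepted only if it does not decrease $G$, so gain is
monotone along the path. Two deliberate choices:

* **Per-update step cap (0.25).** Large single-coordinate jumps would
  let whichever feature is visited first absorb gain that rightfully
  belongs to several correlated features. Capping the step makes the
  per-update gain increments — which are credited to the updated
  feature's variable and are the basis of percent contribution —
  track the optimization path instead of the sweep order. Two equally
  informative independent variables then split contribution close to
  50/50.
* **Active-set screening with a KKT re-check.** Each sweep only visits
  features that are nonzero or violate their optimality condition;
  convergence (sweep improvement `< tol`, default `1e-5`) is only
  declared if no screened-out feature still violates its condition.

A coordinate-descent optimizer was chosen over a generic convex solver
precisely because per-update gain attribution is needed; the objective
is concave plus an L1 term, so the attained optimum is global (tests
verify agreement with exhaustive grid search on small problems to
$10^{-3}$).

Degenerate inputs: a variable constant over training data yields
constant-zero features (reported, never silently informative); a matrix
whose features are all constant is an explicit error; feature
background standard deviations are floored at $10^{-4}$ so a perfectly
separating feature keeps a finite penalty.

### Output scales

Raw probabilities sum to 1 over the evaluation set. The logistic output
is $c\,p/(1+c\,p)$ with $c = \frac{\tau}{1-\tau} e^{H}$, $H$ the entropy
of the fitted raw distribution and $\tau$ the assumed prevalence (0.5 by
default, exposed as a parameter): a cell typical of the landscape under
the uniform model scores exactly 0.5. The cloglog output
$1 - e^{-e^{H} p}$ is also provided and is pointwise at least the
logistic value. All mapped results in this package use the logistic
scale.

## Model selection and evaluation

For each of the 6 × 8 = 48 feature-class × RM candidates, the model is
fitted on all presences and the small-sample AIC computed as
$\mathrm{AICc} = 2k - 2\ln L + \frac{2k(k+1)}{n - k - 1}$, with $k$ the
number of nonzero weights, $n$ the presence count and $\ln L$ the summed
log of landscape-standardized raw scores at the presences. Candidates
with $k \ge n - 1$ are flagged invalid and excluded from ranking. The
minimum-AICc candidate is selected (its delta is 0); exact ties break
toward the higher RM and then the simpler feature class — a parsimony
bias made explicit because the selection rule alone does not decide
ties.

Discrimination is summarized by ROC AUC computed as the rank-sum
statistic (ties count half), with the conventional grading bands:
excellent $[0.9, 1]$, good $[0.8, 0.9)$, average $[0.7, 0.8)$, poor
below. Replicate evaluation holds out a random 25% of presences, refits
on the remaining 75% plus the full background, scores the held-out
presences against the background, and repeats 10 times; the reported map
is the cellwise mean of the 10 logistic maps. The background sample for
testing is the training background (the presence–background convention:
true absences do not exist here, so "AUC" measures separation from
available environment, and its ceiling is well below 1 for a
wide-ranging species).

### Variable screening

A pre-model on all candidate variables (`LQHPT`, RM = 1) yields percent
contributions; Spearman rank correlations are computed on presence rows
(the species' occupied environment — computing them on
presence+background instead is one switch). Screening is greedy: accept
variables in contribution order unless $|r| \ge 0.8$ against an
already-accepted variable; then drop accepted variables below 1%
contribution. Both thresholds are parameters; every exclusion is
recorded with its cause and partner. The 1% floor operationalizes "low
contribution", which otherwise has no canonical value.

### Importance and response curves

Jackknife importance refits with-only-$v$ and without-$v$ models per
variable and reports their regularized training gains next to the full
gain (removing a variable can never raise the regularized gain; tests
assert this). Response curves are marginal by default — sweep one
variable across its training range with the others held at presence
means — with a single-variable-refit mode provided as well, because the
two disagree for strongly correlated predictors. Each curve reports its
argmax (apparent optimum) and the interval where logistic suitability
exceeds 0.5, explicitly empty when the curve never reaches 0.5.

## Classification, areas, centroids

Continuous suitability is classed as unsuitable $[0, 0.2]$, general
$(0.2, 0.4)$, moderate $[0.4, 0.6)$, high $[0.6, 1]$. The 0.2 boundary
belongs to unsuitable (that class is defined as "at most 0.2"); the
0.4/0.6 boundaries are assigned upward. Interval notation at shared
boundaries is inherently ambiguous, so the policy is fixed, documented
and parameterized (`breaks`).

Areas use the spherical cell formula
$A = R^2 \Delta\lambda(\sin\varphi_N - \sin\varphi_S)$ with
$R = 6371.0088$ km, exact on the sphere and additive across latitude
bands; totals are reported in $10^4$ km². A cell is "suitable" for
gain/loss and centroid purposes iff its class is above unsuitable
(suitability > 0.2). Change bookkeeping is exact: net = gained − lost at
full precision, and tabulated values are rounded only for display, so
the printed identity holds on the rounded numbers as well.

Range centroids are cell-area-weighted means of suitable-cell centers in
longitude/latitude (a suitability-weighted mode exists; binary is the
default). Averaging geographic coordinates is a planar approximation
that is adequate at regional extents away from the poles and the
antimeridian — the package's intended domain — and is documented rather
than hidden. Centroid shifts use the haversine distance and initial
great-circle bearing ($R = 6371.0088$ km, via the `geosphere` package),
with compass octants spanning ±22.5° around each direction. For the
first projection period of a scenario chain, the shift from the current
centroid and the shift from the "previous period" coincide by
construction.

## Occurrence handling

Cleaning collapses exact duplicate coordinates (first record kept) and
drops records without coordinates. Thinning then retains at most one
record per cell of the environmental grid itself (2.5 arc-minutes in the
default worlds, ≈ 4.6 km in north–south extent) — guaranteeing at most
one presence per modelling cell, which is the property that prevents
pseudo-replication. Thinning on the analysis grid rather than a metric
5-km grid is a deliberate choice: the two differ with latitude, and only
the former aligns exactly with the model's cell structure. Within-cell
retention is uniform at random under a recorded seed rather than
"first record", to avoid inheriting source-database ordering artifacts.
Thinning is idempotent, and the reported `n_retained` equals the number
of occupied cells.

## The elevation–year trend stage

Per species, ordinary least squares of record elevation on collection
year, fitted separately before and after the year 2000 (records at
exactly 2000 go to the post period; configurable). The slope's two-sided
t-test at $\alpha = 0.05$ drives a direction call (up/down/none);
periods with fewer than 3 usable records or no year variance are
reported as such rather than fitted. The split year is fixed, not
estimated — this stage is a descriptive comparison, not a breakpoint
model.

## The synthetic world

The generator exists so that every stage can be tested against known
ground truth, offline:

* **Layers** are deterministic trends (gradients, a north–south ridge,
  radial bumps) plus Gaussian-smoothed seeded white noise. Smoothed
  noise gives realistic short-range spatial autocorrelation at desk
  scale without the cost of a full Gaussian-process simulation; it does
  not reproduce long-range teleconnections or anisotropy of real
  climate fields.
* **Climate–elevation covariance**: a layer requesting correlation $r$
  with elevation is mixed from the standardized elevation field and an
  elevation-orthogonalized noise field, so the empirical correlation is
  attained exactly.
* **Truth**: suitability is the inverse logit of a linear/quadratic form
  in standardized layers; a variable with a stated optimum contributes a
  concave parabola peaking there, so the "right answer" for
  response-curve recovery is known by construction.
* **Sampling**: presences are a multinomial draw proportional to
  suitability (optionally times a bias layer) at cell centers, with
  years uniform over 1950–2020, or rank-linked to elevation when the
  trend stage needs signal.
* **Futures** are additive layer shifts; untouched layers (elevation,
  human footprint) are carried over bit-identical, matching the usual
  static-human-pressure assumption of scenario projection.

What passing tests on this world do **not** show: robustness to
coordinate error, sampling bias beyond the explicit bias layer,
non-additive climate change, categorical predictors, or extrapolation
far outside training bounds (features are clamped, which flattens
responses beyond the training range rather than extrapolating them).

### Recovery properties exercised by the tests

At 200 presences on a 50 × 50 world: the response-curve optimum of a
quadratic truth is recovered within 10% of the variable's range in at
least 8 of 10 seeds; a pure-noise variable's with-only jackknife gain
stays below 0.05 nats; and a positive shift of the temperature layer
moves the suitable-range centroid toward higher true elevation in at
least 4 of 5 seeds.

## Problem sizes and numerical choices

The shipped demonstrations and the acceptance script use a 60 × 60 grid
(3600 cells), 250 sampled presences (230-odd after thinning), 2000
background cells, 15 hinge and 10 threshold knots per variable, the full
48-candidate tuning grid and 10 evaluation replicates — sizes chosen so
a complete run finishes in well under a minute on one CPU while leaving
every statistical property measurable. Defaults inside the functions
remain the field-standard ones (50/20 knots, 10,000 background). Other
numerics: convergence tolerance $10^{-5}$ nats on the sweep gain
improvement; at most 1000 sweeps; log-sum-exp throughout; curvature
floored at $10^{-10}$ in coordinate steps.

## Known limitations

* No reprojection or resampling: all rasters must already share one
  grid; mismatches are errors, not silently resampled.
* No categorical features; class-coded soil variables are treated as
  numeric.
* No spatial cross-validation (block/checkerboard), omission-rate or
  Boyce metrics; evaluation is AUC-based.
* Centroid averaging in lon/lat and single-grid areas make the
  suitability-change stage a regional-scale tool, not a global one.
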