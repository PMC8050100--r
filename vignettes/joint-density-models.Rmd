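---
title: "Joint visual and passive-acoustic cetacean density models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint visual and passive-acoustic cetacean density models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cetadens)
```

## The problem

Shipboard line-transect surveys and fixed passive acoustic monitoring (PAM)
observe cetacean populations in complementary ways. A survey vessel covers a
large area but only during fair-weather (mostly summer) cruises, and only
sees animals at the surface; a seafloor acoustic sensor hears echolocating
animals around a single point continuously, through every season, but never
moves. Species distribution models trained on either data type alone
inherit its blind spots: visual-only models never see winter conditions,
acoustic-only models never see oceanographic conditions that do not pass
over the handful of sensor sites.

`cetadens` implements a pipeline for putting both data types on a common
density scale (animals per 1000 km²), attaching a shared set of
environmental covariates, and fitting distribution models to acoustic-only,
visual-only, or pooled ("joint") training data with two frameworks — a
Tweedie generalized additive model (GAM) and an averaged ensemble of small
neural networks (NN) — so that their out-of-sample skill can be compared by
root-mean-square error (RMSE). A synthetic-data generator with a known
density surface makes every stage testable by parameter recovery.

## Per-modality density estimation

### Visual branch (distance sampling)

Transect lines are divided into segments of at most 10 km, treated as point
estimates at their midpoints. For one species, all perpendicular sighting
distances define a truncation distance $w$ — the empirical 95th percentile
(linear-interpolation quantile) — and a detection function $g(x)$ fitted by
maximum likelihood on the distances within $[0, w]$ and selected by AIC
among four candidate forms: uniform, half-normal
$\exp(-x^2/2\sigma^2)$, hazard-rate $1 - \exp(-(x/\sigma)^{-b})$, and
hazard-rate with a second-order polynomial adjustment
$(1 + a_2 (x/w)^2)$, parameterized so $g(0) = 1$. The monitored area of a
segment of length $L$ is

$$A_{vis} = 2 w L,$$

and the segment density, with $\hat G_{tot}$ the summed best group sizes of
its retained sightings, $g(0)$ the trackline detection probability
(a per-species input, default 1), and
$\hat P_{vis} = \tfrac1w \int_0^w g(x)\,dx$:

$$\hat D^V_t = \frac{1000 \, \hat G_{tot}}{A_{vis} \cdot g(0) \cdot \hat P_{vis}}.$$

Two ordering choices are deliberate and flagged as assumptions: $w$ is
computed *before* detection-function fitting, the same $w$ enters
$A_{vis}$, and sightings beyond $w$ are excluded from $\hat G_{tot}$.
The likelihood is maximized with a small multi-start grid over $\sigma$
(and box constraints keeping $b \in [1, 20]$, $a_2 \in [-1, 5]$) to avoid
local optima; invalid parameter regions receive a large finite penalty so
the box-constrained optimizer never sees a non-finite objective. A form
whose optimizer fails is dropped with a warning rather than failing the
whole fit.

### Acoustic branch (group counting)

Detections are binned into UTC calendar days (sensors record continuously
and carry no natural timezone), and only days with a full 24 h of recording
effort are used — enforced as `effort_hours >= 23.999` to absorb rounding
in effort logs. With $n_{kt}$ the number of 5-minute windows at site $k$ on
day $t$ in which a group was detected, $T_{kt}$ the windows sampled,
$\hat c_k$ the site false-positive fraction, $\hat s$ the mean group size,
$w$ the maximum horizontal detection range, $\hat P_k$ the probability of
detecting a group within $w$, and $\hat P_v$ the probability that a group
is vocally active in a window:

$$\hat D^A_{kt} = \frac{1000 \, n_{kt} (1 - \hat c_k)\, \hat s}
 {\pi w^2 \hat P_k \hat P_v T_{kt}}.$$

All five site/species parameters are inputs, not estimated here; they come
from the acoustic calibration literature for each species and instrument.

## Environmental covariates

Nine covariates drive the models: SSH (m), SST (°C), CHL (mg/m³), MLD (m),
Upwell (vertical velocity at 50 m, m/s), SAL (PSU), CUR (m/s), and the
distances (km) to the nearest cyclonic (`posEddyDist`) and anticyclonic
(`negEddyDist`) eddy. CHL, MLD and CUR are natural-log transformed to
reduce skew. Bathymetry, season, Julian day and anthropogenic covariates
are excluded by construction: they are confounded with fixed sensor
locations or with the seasonal timing of cruises, so one modality or the
other cannot sample them.

Each observation is matched to the nearest grid node by great-circle
distance (haversine, $R = 6371$ km) and the nearest time slice by absolute
day difference, within a tolerance of ±8 days (the coarsest product
emulated is an 8-day average); ties break toward the earlier slice and the
lower node index, making matching deterministic and idempotent. Eddy
centres are local extrema of the SSH anomaly (field minus its spatial mean
— a no-op when the product is already an anomaly) under an 8-neighbour
rule, thresholded at |anomaly| ≥ 0.10 m by default. No published eddy
algorithm is prescribed for this step, so the threshold rule is exposed as
a configuration knob rather than hidden. Records with missing covariates
(time gap, or no eddy of a polarity anywhere in a slice) are dropped from
model tables with a logged count, never imputed.

## Model frameworks

Both frameworks consume the same model table — a `density` response plus
the nine (transformed) covariates — store the training min/max of every
covariate, and refuse to predict rows outside that envelope (out-of-range
masking; masked cells appear as whitespace on maps).

**GAM.** `density ~ s(cov, bs = "ts", k = 3)` over all nine covariates,
Tweedie family with log link, fitted by mgcv with REML (the Tweedie power
$p \in (1,2)$ is estimated unless fixed via `tweedie_p`, in which case
GCV is used). The "ts" shrinkage penalty lets uninformative smooths shrink
toward zero; after the first fit, terms with effective degrees of freedom
below 0.5 *or* approximate p-value above 0.05 are removed and the model is
refit once. The removal criterion is not prescribed anywhere, so both
thresholds are arguments. The 3-knot basis is deliberately small: richer
bases overfit the data-poor edges of the covariate distributions.

**NN ensemble.** Single-hidden-layer networks (nnet) with 9 inputs, one
output, weight decay $10^{-4}$, at most 500 training iterations, initial
weights uniform on $[-0.7, 0.7]$; inputs rescaled to $[-1, 1]$ by the
training ranges ($x' = 2(x - \min)/(\max - \min) - 1$), response
$\log(\text{density} + \delta)$ with $\delta = 1$ (zeros dominate density
tables; the offset is an argument). For each hidden size $h \in
\{4, \dots, 14\}$, 25 independently initialized networks are trained and
their *outputs* averaged; the hidden size minimizing RMSE on a held-out
evaluation table is selected. Two consequences of that procedure are worth
stating plainly:

* Averaging happens on the network-output (log) scale, and only the
  averaged output is back-transformed, $\hat D = \max(e^{\bar y} - \delta,
  0)$. Averaging back-transformed member predictions instead lets a single
  member that extrapolates high on the log scale dominate the mean through
  the exponential; in null simulations this inflated RMSE by orders of
  magnitude. The per-row ensemble `sd` is reported across member outputs,
  i.e. on the log scale.
* Hidden-size selection on the evaluation table leaks test information
  into one discrete choice. This is kept deliberately — it reproduces the
  established procedure — and the fit emits a warning saying so.

The network cost function is penalized least squares on the log response
(the Gaussian-likelihood reading of "maximum conditional likelihood" for a
continuous response); member seeds are derived deterministically from the
master seed, so fits are bit-reproducible. Variable importance uses the
Olden connection-weight product (sum over hidden nodes of input-to-hidden
times hidden-to-output weights, averaged over members, signed) for
networks, and effective degrees of freedom (zero for removed terms) for
GAMs.

**Joint training** concatenates the two modality tables without weighting:
the package assumes similar numbers of observations per modality and equal
confidence in each. If one modality should dominate, subsample before
calling `run_experiment`.

## Evaluation

`rmse()` implements $\sqrt{\tfrac1N \sum_n (y_n - \hat y_n)^2}$ with
masked pairs excluded pairwise. `run_experiment()` fits every framework ×
training-set combination, scores each on the combined visual + acoustic
test table, and flags the per-framework minimum — a 3 × 2 comparison per
species. Because each model masks a different set of out-of-range test
rows, the RMSE cells are computed on slightly different subsets; the
per-modality diagnostic columns (`rmse_visual`, `rmse_acoustic`,
`n_masked`) are emitted so this is visible, and the per-cell counts should
always be read alongside the scores.

## The synthetic study system

The generator emulates the statistical structure the estimators assume,
not the ocean:

* **Fields**: each covariate is a climatological mean plus a deterministic
  seasonal cycle (SST amplitude 4 °C peaking mid-July) plus a smooth
  Gaussian random field (random low-frequency Fourier features) evolving
  as an AR(1) process in time (day-to-day correlation 0.8). CHL, MLD, CUR
  are generated on the log scale, hence strictly positive. SSH is a
  constant background plus Gaussian-bump eddies
  $A\exp(-d^2/2r^2)$ advected linearly by a drift velocity, plus noise.
* **Truth**: $D = \exp(\alpha + \sum_c f_c(\text{cov}_c))$, evaluated per
  cell and day; deterministic given the fields.
* **Visual surveys**: groups placed per segment as a homogeneous Poisson
  process with intensity $D/\bar s$ per km² (density at the segment
  midpoint — matching the point-estimate treatment of segments) over the
  $2W$ strip, thinned by $g(0) \cdot g(x)$ with $x$ uniform on $[0, W]$;
  group sizes zero-truncated Poisson with mean $\bar s$.
* **PAM**: each window records a true detection with probability
  $q = \min(1, (D/\bar s)\pi w^2 \hat P_k \hat P_v)$ and a false one with
  probability $q\hat c_k/(1-\hat c_k)$, so the realized false fraction is
  $\hat c_k$ in expectation and the $(1-\hat c_k)$ correction is exactly
  the right inverse; a day's count is binomial over its windows, at most
  one detection per window. Windows are exchangeable within a day — no
  diel pattern is simulated, since none is prescribed for the estimator.

What passing recovery tests does *not* show about real data: real
detection functions are not drawn from the candidate set; real acoustic
parameters ($\hat c_k, \hat P_k, \hat P_v$) are themselves uncertain
estimates, while here they are known inputs; real covariates are measured
with error and gaps; and real densities are not log-additive in the
covariates. The tests establish that the estimators and models invert
their own assumptions correctly, not that those assumptions hold at sea.

## Problem sizes and numerical choices in the test suite

The recovery and comparison tests run at sizes chosen to make their
statistical expectations sharp while keeping the suite quick:

* Plug-in estimator oracles: 1000 random parameter draws, agreement to
  1e-12 with independently ordered arithmetic.
* Detection recovery: 100 replicates × 1000 half-normal distances
  (σ = 2 km, truncation 8 km); AIC picks half-normal in well over 70% of
  replicates and the median relative σ error is ~2%.
* Estimator consistency: 500 visual segments at D = 20 (within 15%), 1000
  PAM site-days at D = 5 (within 10%); mis-specifying the false-positive
  rate to zero inflates the acoustic mean by exactly 1/(1 − 0.2) = 1.25.
* NN recovery: 1500/500 train/test rows, full 4–14 hidden search, 25
  members.
* GAM shrinkage recovery: 50 replicates, 400 rows, one informative
  covariate among nine.
* Null comparison (constant truth): 600 training rows per modality. At a
  few hundred rows the networks still chase noise — the overfitting
  susceptibility on zero-inflated responses is a known behaviour of this
  framework — and the six experiment cells only converge to within 5% of
  one another once training data suffice.
* Joint-vs-visual experiment: 20 replicates of a two-year scenario
  (300 summer visual training segments, 3 PAM sites every 3rd day, test =
  150 summer segments + year-round site-days) in which density falls with
  SST (winter peak) and rises with SSH near anticyclonic eddies. Summer
  surveys truncate the SST range; fixed sites truncate the SSH range; the
  joint model sees both and beats the visual-only model on held-out RMSE
  in every replicate observed, comfortably above the 60% the test
  requires.

Degenerate inputs are errors, not silent defaults: empty grids or date
spans, non-positive segment lengths, $c_k = 1$, zero denominators,
constant (degenerate) predictors at the scaling stage, overlapping effort
intervals, and unknown species or site labels all fail loudly. Ties in
quantiles, nearest-node and nearest-slice matching, and equidistant eddy
centres all break deterministically, which is what makes the
fixed-seed pipelines bit-reproducible.

## Known limitations

* Box (per-covariate) masking cannot flag joint extrapolation: a test
  point can be inside every marginal range yet far from the training
  cloud, and exponential back-transforms make NN predictions there
  volatile. The ensemble `sd` is the available warning signal.
* Detection-function selection on truncated, small samples occasionally
  picks a hazard-rate form for half-normal data, biasing $\hat P_{vis}$
  and hence single-run mean densities by ~15–20%; across seeds the
  estimator is unbiased.
* RMSE comparisons across models with different masked sets are not
  strictly like-for-like; read the counts.
* The acoustic estimator assumes the small-$q$ regime (at most one group
  per window); the simulator warns when $q$ saturates.
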