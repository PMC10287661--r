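---
title: "Charting infant subcortical growth: models, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charting infant subcortical growth: models, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growmap)
```

growmap implements the statistical core of a longitudinal infant
neuroimaging analysis: population growth trajectories of the six bilateral
subcortical structures (thalamus, caudate, putamen, pallidum, hippocampus,
amygdala) over the first 27 postnatal months, uncertainty for interval
growth rates, vertex-wise surface-area expansion maps, and mixed-model
associations between morphometry and Mullen early-learning scores. Because
the motivating cohorts are access-controlled, the package ships a synthetic
cohort generator with known ground truth; every inferential claim the
package makes is exercised against that truth in the test suite.

## The trajectory model

For subject $i$ with volume (or vertex area) $y_i(t)$ at age $t$ days,

$$y_i(t) = s_i + \beta_T\, T_i(t) + f(t) + \Delta(t)\, g_i + \alpha_i + e_i(t),$$

where $s_i$ is a fixed site effect (reference coding, first level as
baseline), $T_i(t)$ the per-scan intracranial volume (ICV, standardized
internally), $f(t)$ a penalized cubic B-spline smooth of age, $\Delta(t)$ a
penalized sex-deviation smooth times the male indicator $g_i$,
$\alpha_i \sim N(0, \tau_\alpha)$ a subject random intercept, and
$e_i(t) \sim N(0, \sigma^2)$ white noise. Dropping
$\Delta(t) g_i$ gives the sex-free variant used for per-vertex area
trajectories.

**Basis and penalty.** The smooths use cubic B-splines with boundary knots
at the full study span (0–810 days; 1 month = 30 days throughout) and
interior knots at quantiles of the observed ages. The penalty is a
second-order *divided* difference of the coefficients with respect to the
basis's Greville abscissae. With unequal (quantile) knots this is the
choice that makes the penalty null space exactly the straight lines
$\{1, t\}$, so the infinite-smoothing limit of the fit is the ordinary
least-squares line — plain second differences of the coefficients do not
have this property off a uniform grid. Each smooth carries a sum-to-zero
constraint over the observed ages for identifiability, and the constrained
penalty is eigen-decomposed into an unpenalized linear direction (kept as a
fixed effect) plus independently penalized range-space directions — the
standard mixed-model representation in which the smoothing parameter
$\lambda_j$ is the ratio $\sigma^2/\tau_j$ of noise to smooth-coefficient
variance.

**Estimation.** $\lambda$s and variance components are selected by
maximizing the marginal likelihood (ML, the default; REML is available as
an option). All likelihood quantities are computed from per-subject
sufficient statistics with Woodbury identities, so one evaluation costs
$O(S P^2)$ for $S$ subjects and $P \approx K + 10$ coefficients — there is
never an $n \times n$ factorization, which is what makes 200-cohort
calibration studies and per-vertex bootstraps affordable. The optimizer is
box-constrained quasi-Newton (L-BFGS-B) on the log variance ratios with
three dispersed starts (all 0, all $+3$, all $-3$ on the log scale) and a
relative tolerance near machine precision; the accepted optimum is asserted
to be no worse than every start. Subjects with a single scan are retained
(about half the default cohort); they inform the fixed effects and the
total variance while the repeat scans identify the intercept/noise split.

**Default basis dimensions** are $K = 10$ for $f(t)$ and $K = 5$ for
$\Delta(t)$; both are arguments. With 6 interior knots over 27 months the
age smooth can track the rapid early saturation of subcortical growth while
the penalty guards the sparsely sampled first weeks.

**Population curves.** `predict_curve()` reports the population-level
trajectory at the reference profile: site coefficients averaged with
observed site frequencies, the requested sex stratum (or a
frequency-weighted pool), and ICV fixed at the cohort-mean ICV-vs-age
trajectory. That reference ICV curve is itself estimated with the package's
sex-free spline model (ICV as the response). An earlier implementation used
binned means with linear interpolation; it left a systematic distortion of
tens of mm$^3$ at the birth boundary, where ICV curvature is steepest —
large enough to corrupt normalized curves anchored at $Y(0)$ — so the
spline reference replaced it. A side benefit is that
`derivative_curve()` (the exact analytic derivative of the prediction,
scaled to volume/month) is smooth rather than kinked at bin edges.
Confidence bands are $\pm 1.96$ pointwise SEs from the penalized
coefficient covariance. `normalized_curve()` divides by the predicted
volume at term birth, so its value at age 0 is exactly 1.

## Interval growth rates and the bootstrap

The interval growth rate between months $t_1 < t_2$ is
$[Y(t_2) - Y(t_1)]/Y(t_1)$ on the population curve, tabulated over the nine
standard ranges (0–3, 3–6, 6–9, 9–12, 12–18, 18–24, 0–6, 0–12, 0–24
months). Uncertainty comes from a stratified bootstrap for longitudinal
data: whole subjects are resampled with replacement — all scans of a drawn
subject move together — within strata that preserve both design margins,
by default site crossed with the number-of-scans category $\{1, 2, 3{+}\}$.
The Z-statistic for a volume change is
$|Y(t_2) - Y(t_1)| / \mathrm{SD}[Y(t_2) - Y(t_1)]$ with the SD taken over
replicates (moment SD, not percentile-based), a standard-normal two-sided
p-value, and Bonferroni correction over the table's simultaneous cells
(structures $\times$ intervals per hemisphere by default; the count is an
argument).

**Fixed-$\lambda$ versus refitted replicates.** By default each replicate
is refitted by penalized GLS with the smoothing parameters and variance
ratios held at their point estimates; `refit_lambda = TRUE` re-selects them
per replicate (warm-started at the point estimate). Simulation under a
flat-growth null shows the two regimes serve different quantities: for
*interval differences* of the curve the fixed-$\lambda$ replicate SD is
essentially exact (type-I error of the Z-test near nominal), while for the
*level of the curve at the span boundary* (day 810) fixed-$\lambda$
replicates miss the smoothing-parameter component of the variance and
undercover; the refitted bootstrap restores it. The package therefore uses
the fast fixed-$\lambda$ default for growth tables and recommends
`refit_lambda = TRUE` when reporting percentile intervals for boundary
values. Sex differences are tested pointwise (per grid age) as the
bootstrap Z of the male-minus-female fitted difference; the curve-wise
alternative is not implemented. The asymmetry index of bilateral curves is
$(L - R) / ((L + R)/2)$, positive leftward.

## Vertex-wise expansion maps

The local area of a vertex is one third of the summed areas of its incident
triangles, which conserves total surface area exactly and is invariant to
rigid motion; the Voronoi-area alternative is not implemented. Per-vertex
trajectories use the sex-free model with a shared basis and design and
per-vertex smoothing parameters; the monthly expansion rate is the relative
derivative $(dA/dt)/A(t)$ per 30-day month, comparable across structures of
different sizes (absolute rates are available by flag). Vertices whose
optimizer fails are masked out of every downstream map.

**High-/low-growth detection.** At each month, candidates are the top and
bottom 20% of vertices by rate; the quantile is taken by rank with ties
broken by vertex index, so exactly $\lceil qV \rceil$ vertices qualify per
tail, deterministically. Each candidate's bootstrap replicate rates are
compared against the cross-vertex *median* of the point rates (recomputed
per month): $t = (\bar r_{\mathrm{boot}} - \mathrm{median}) /
\mathrm{sd}(r_{\mathrm{boot}})$ with $B - 1$ degrees of freedom. The
bootstrap SD here estimates the sampling SD of the vertex's rate — the
statistic deliberately does *not* divide the SD by $\sqrt{B}$, which would
treat replicates as independent observations and reject almost everywhere
under a uniform-growth null; with the estimator-SD convention the labelled
fraction under the null stays below the FDR level. p-values are
Benjamini–Hochberg adjusted across the tested candidates of the structure
(not pooled across structures), and significant candidates above/below the
median are labelled high/low.

## Brain–behavior association

For each of the six Mullen scores (GM, FM, VR, RL, EL, ELC) and each
structure, the model is

$$\mathrm{score} \sim \mathrm{age} + \mathrm{sex} + \mathrm{site} +
\mathrm{income} + \mathrm{edu} + \mathrm{ICV} +
\log(\mathrm{vol}/\mathrm{ICV}) + (1 \mid \mathrm{subject}),$$

with every covariate and the predictor standardized to mean zero and unit
variance, fitted by REML through lme4, and the predictor tested with
Satterthwaite's approximate t-test (lmerTest). When the random-intercept
variance is singular — e.g. one observation per subject — the model falls
back to OLS with $n - p$ degrees of freedom, with a warning. All 36
structure-score cells are computed; BH-FDR is grouped within each score
across the six structures by default (pooling all 36 is an option, since
the original grouping is not fully determined). Nested-model comparison
against the covariates-only null uses the joint Satterthwaite F contrast of
the added log-ratio coefficients in the ML-fitted full model. The
vertex-level variant replaces the volume ratio with the standardized local
area of one vertex, joins behavioral visits to mesh scans by nearest age
within a 45-day window (configurable), keeps the random intercept by
default (a flag reproduces the fixed-effects-only form), and adjusts BH
across the vertices of the structure.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` reproduces the *design* of a two-site longitudinal
infant study: 231 subjects by default (the reference cohort size), 55/33/12%
with 1/2/3 scans (so 45% have two or more), a female share of 0.545, visit
ages on integer days drawn without replacement per subject from a mixture
that is densest at 3–15 months with an early-infancy component and a
uniform tail — the exact visit schedule of any real study is not
replicated. Growth truth: five structures follow a log-saturating curve
$a\,(1 + G \log(1 + t/c)/\log(1 + 810/c))$ with birth volumes and total
growth fractions chosen to match published infant ranges (e.g. thalamus
$\approx$ 3400 mm$^3$ at birth growing ~45%, caudate roughly doubling); the
amygdala analog grows linearly. Male offsets grow linearly from zero at
birth for all structures except the caudate and amygdala analogs (which
carry none); site offsets are 1% of birth volume; ICV co-grows from 450 to
~1080 cm$^3$ and couples to volumes through a deviation term. Noise and
subject-intercept SDs are *fractions of each structure's birth volume*
(defaults 2.5% and 4%) because the structures span an order of magnitude in
size. Meshes are subdivided icosahedra with a radial growth field, planted
antipodal high- (2$\times$) and low-growth (0.5$\times$) caps, per-subject
size factors and multiplicative vertex jitter. Mullen scores are linear in
standardized household covariates and the standardized bilateral log
volume-to-ICV ratios with planted per-SD coefficients, a subject intercept
and noise; ELC is generated directly from its own coefficient column rather
than aggregated from subdomains.

Passing tests on these data therefore demonstrate that the estimators
recover the truth under the *assumed* model — Gaussian noise, additive site
effects, exchangeable subjects, spherical topology with exact vertex
correspondence. They do not validate segmentation quality, registration,
non-Gaussian artifacts, scanner drift, or informative missingness, none of
which the generator emulates.

## Numerical choices and degenerate inputs

* Variance-ratio search is bounded to $e^{\pm 18}$; a fit reaching the
  lower bound simply means "effectively linear" (maximal smoothing).
* The fitted coefficient vector is checked against its penalized normal
  equations (relative residual $< 10^{-8}$ stored on the model).
* Single-site cohorts drop the site effect with a message; single-sex data
  refuse the sex-aware model; fewer than 20 scans or fewer than two
  subjects with repeats warn.
* Replicates that fail to refit are dropped and logged; more than 5%
  failures abort. Bootstrap draws, cohort generation and mesh jitter all run
  in private RNG streams, so identical seeds give byte-identical outputs
  and the caller's RNG state is untouched.
* Degenerate (zero-area) triangles are rejected by index on input meshes
  and re-jittered (with a log message) during synthesis.

## Problem sizes used in the checks

The calibration studies in the test suite use cohorts of 150 subjects with
200 bootstrap replicates and 200 simulation rounds for trajectory and
Z-test calibration, 100 rounds for FDR control of region detection on
42-vertex spheres, and 162-vertex spheres for patch recovery — sizes at
which the Monte-Carlo error of each checked proportion is several times
smaller than the width of its acceptance band, while a full run of the
suite stays comfortably within an ordinary desktop session.

## Known limitations

* The ICV reference curve's estimation uncertainty is not propagated into
  trajectory confidence bands.
* Residuals are assumed white within subject; no autocorrelation structure
  is offered.
* The site effect is additive only (no site-by-age interaction), matching
  the model being implemented.
* Percentile intervals at the span boundary need `refit_lambda = TRUE` to
  reach nominal coverage (see above); the fixed-$\lambda$ default is
  calibrated for interval growth differences.
* No tensor-product or spatial smooths; vertex models are fitted
  independently, so spatial correlation of rates enters only through the
  shared subject resampling.
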