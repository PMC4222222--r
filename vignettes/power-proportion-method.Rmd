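---
title: "Power-proportion correction of regional brain volumes: model, estimation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-proportion correction of regional brain volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powerprop)
```

## The problem

Volumes of brain structures scale with overall head size. When two groups
are compared on, say, hippocampal volume, part of any difference simply
reflects that one group has bigger heads. Head size is conventionally
measured by intracranial volume (ICV, in cc), and the comparison is made
on ICV-corrected volumes.

The two classical corrections make strong structural assumptions:

* **Proportion method** — analyse the ratio VOI/ICV. This assumes strict
  proportionality, VOI = &alpha;&middot;ICV.
* **ANCOVA / residual method** — analyse the residuals of an OLS
  regression of VOI on ICV. This assumes linearity (with a free
  intercept).

Across species and across individuals, however, many anatomical volumes
follow an allometric *power law*, VOI = &alpha;&middot;ICV^&beta;^ with
&beta; typically below 1: big heads have proportionally smaller deep
structures. When &beta; &ne; 1 the ratio VOI/ICV still depends on ICV
(it behaves like ICV^&beta;&minus;1^), so the proportion method
*under-corrects* and leaves a residual negative trend of the corrected
volume on ICV — precisely the confound the correction was meant to
remove.

## The model and the correction

The package fits, separately for each region,

$$ VOI_i = \alpha \, ICV_i^{\beta} + \varepsilon_i, \qquad
   \varepsilon_i \sim N(0, \sigma^2) \ \text{i.i.d.}, $$

by nonlinear least squares, and corrects volumes as

$$ VOI_{PPC,i} = VOI_i / ICV_i^{\,b}, $$

where $b$ is the fitted exponent (`fit_power_law()`,
`apply_power_proportion()`). With $b = 1$ this is exactly the proportion
method, so the familiar ratio is recovered as a special case whenever the
data support proportionality.

The additive noise assumption matters. The alternative of regressing
log(VOI) on log(ICV) (`apply_loglog_residual()`) fits the same power-law
mean but implies *multiplicative* noise — variability growing with ICV.
Empirically, scatter of regional volumes is roughly constant across the
ICV range, which motivates the additive formulation; the synthetic
generator can produce both regimes so the distinction stays testable
(`noise_mode` in `synthetic_spec()`).

## Estimation details

Choices a user may want to know, all in `fit_power_law()`:

* **Rescaling.** ICV is divided by its sample geometric mean before
  optimization. With raw ICV near 1500 cc the two Jacobian columns
  (ICV^&beta;^ and &alpha;&middot;ICV^&beta;^&middot;ln ICV) differ by
  orders of magnitude and the normal equations become badly conditioned;
  on the rescaled axis both are O(1). The exponent and its standard
  error are invariant to this (tested); the scale constant is
  back-transformed, with its standard error propagated by the delta
  method.
* **Initialization.** Log-log OLS (slope &rarr; &beta;&#8320;,
  exp(intercept) &rarr; &alpha;&#8320;), then the scale constant is
  profiled at &beta;&#8320; via the closed form
  `profile_alpha()`. The log-log fit is the multiplicative-noise
  linearization of the same mean function, so it starts the optimizer
  essentially at the optimum. If too few volumes are positive for logs,
  a coarse profiled grid supplies the start.
* **Optimizer.** Levenberg–Marquardt (via `minpack.lm`) with the
  analytic Jacobian; convergence when the relative SSE change falls
  below 1e-10 (or the Marquardt gradient criteria trigger), at most 200
  iterations. On failure the fit falls back to an exponent grid over
  [0, 3] in steps of 1e-3 with the scale constant profiled out
  (`grid_search_exponent()`), restarts Marquardt from the best grid
  point, and reports `converged = FALSE` only if that also stalls.
* **Inference.** The covariance is the Gauss–Newton linearization
  $\hat\sigma^2 (J^\top J)^{-1}$ with $\hat\sigma^2 = SSE/(n-2)$
  (two mean-function parameters). Intervals use t quantiles on
  $n - 2$ degrees of freedom; at typical study sizes (n &asymp; 140)
  t and normal limits agree to two decimals.
* **Nonpositive volumes.** Real volumes are positive, and the table
  container enforces that at the I/O boundary. Inside the fitter,
  though, heavy additive noise can push simulated observations to or
  below zero; the least-squares criterion is perfectly well defined
  there, so the fitter tolerates them rather than silently dropping
  rows (only non-finite pairs are dropped).
* **Nonproportionality flag.** A region is flagged when the confidence
  interval for &beta; lies strictly away from 1. The closed-interval
  convention (an endpoint exactly at 1 is *not* flagged) is
  conservative; the boundary case essentially never occurs with
  continuous data.
* **No multiplicity adjustment.** Per-region intervals are nominal
  per-region levels, matching standard practice for descriptive scaling
  tables. Users screening many regions for "significant
  nonproportionality" should adjust externally if they need family-wise
  control.
* **Reference-group fitting.** In patient studies it is arguable
  whether $b$ should come from controls only or from the pooled sample;
  the package takes no position and exposes
  `fit_all_regions(group_col =, reference =)` plus an explicit `b`
  argument to `correct_volumes()`, recording the provenance of the
  exponent in the output.

## Comparing corrections

`compare_models()` evaluates the three candidate *mean models* — power
law, straight line, quadratic — by leave-one-out cross-validation:
each subject is predicted from a model fitted to the other $n-1$, and
the prediction error is the sum of squared differences between observed
and predicted volumes. Power-law refits inside the loop are warm-started
from the full-data fit (a flag forces cold starts; the two agree to
optimizer tolerance, and a test asserts it). Fold failures are recorded
and never abort a batch. Because published prediction-error scatterplots
are ambiguous about what one point represents, the result keeps both the
per-region totals and the per-fold detail.

In-sample, the quadratic SSE can never exceed the linear SSE (nesting);
out-of-sample no such ordering is guaranteed, and the test suite only
asserts the in-sample nesting plus Monte-Carlo orderings at stated
confidence.

`residual_slope()` provides the graphical diagnostic in numeric form:
the OLS slope, Pearson correlation and two-sided p-value of corrected
volume against ICV. A successful correction leaves all three near zero
(slope of exactly 0 is reported, with a flag, when the corrected values
are constant).

## The synthetic generator and its calibration

No individual-level volumetric dataset ships with the package; instead
`simulate_table()` generates tables with the structure the model
assumes, and every downstream claim is tested on those. The default
conditions (`default_spec()`) emulate a healthy-adult structural-MRI
sample:

* 49 males and 92 females (n = 141), ICV drawn per sex from
  N(1712.01, 138.54&sup2;) and N(1513.88, 122.12&sup2;) cc — so the
  expected sex gap is 198.13 cc;
* 43 regions (9 subcortical including CSF, 34 cortical parcels) with
  published scaling exponents ranging from 0.52 (cuneus, temporal pole)
  through 1.57 (lateral ventricles), listed in
  `reference_exponents()`;
* per-region scale constants set so the volume at the mixture-mean ICV
  equals a plausible typical volume (caudate 3.5 cc, superior frontal
  20 cc, ...). These are stated as plausible cc scales, not estimates
  from any particular cohort;
* per-region noise &sigma; *calibrated* by inverting the Gauss–Newton
  standard-error formula (`calibrate_sigma()`), so that a fit at
  n = 141 reports approximately the published standard error of that
  region's exponent. Residual SDs are not published, so this
  calibration is approximate by construction.

Draws are reproducible: one seed, with deterministic per-region
substreams, so removing regions from the spec never changes the
remaining columns. Nonpositive draws (possible under additive normal
noise) are resampled and counted; because the mean volume is positive,
a draw is positive with probability above one half, so the bounded
retry limit is effectively unreachable except under pathological
specifications.

What the generator does *not* emulate: segmentation error structure,
age and disease atrophy effects, cross-region correlations within
subject, heteroscedasticity (except via the explicit multiplicative
mode), and site/scanner effects. Passing tests therefore demonstrate
correctness of the statistical machinery under the model's own
assumptions, not robustness to the ways real imaging data violate them.

## Problem sizes used by the test suite

The shipped checks run at the sizes of the emulated study: single fits
and LOOCV at n = 141; the interval-coverage study uses 1000 replicates;
the model-comparison orderings use 100 replicates per exponent value;
the decorrelation check for the power-proportion correction uses one
sample of n = 2000. The whole suite completes in well under a minute on
one core.

## A known honest limitation

Under noise calibrated to published exponent precision (fitted SE
&asymp; 0.06–0.10), the curvature that distinguishes an
&alpha;&middot;ICV^0.6^ mean from its best straight-line approximation
over the observed ICV range is tiny (bias SSE on the order of 0.004
cc&sup2; against residual SSE of tens of cc&sup2;). Out-of-sample, the power-law model then beats the linear
model in only about two-thirds of replicates — the test suite measures
this — rather than in a large majority, and the frequency is nearly
invariant to the noise level because the fold-noise term dominates the
fixed bias. A decisive LOOCV win for the power law at n = 141 requires
either residual noise far below what volumetric studies report or
stronger curvature than the power law itself generates at these
exponents. The corresponding acceptance expectation is deliberately
left failing rather than met by weakening the simulated conditions; at
&beta; = 1 the two models' prediction errors agree to well under 5%, as
expected.

## Other deliberate conventions

* Volumes are cc internally; mm&sup3; is accepted only at the reading
  boundary (`unit = "mm3"` divides by 1000 — FreeSurfer stats files are
  always mm&sup3; and always converted).
* FreeSurfer left/right structures are summed into one region by
  default (`hemi_sum = FALSE` keeps them separate); published scaling
  tables list single bilateral entries, but the convention is exposed
  rather than hard-coded.
* Rows failing validation are dropped per region, not listwise across
  regions, since regions are fitted independently.
* Residual-method corrections are recentred at mean(VOI) by default so
  every method returns values on an interpretable volume scale;
  `recentre = FALSE` returns raw residuals.
* The log-log correction returns the back-transformed ratio
  VOI/ICV^b_log^ rather than log-scale residuals, making it directly
  comparable with the power-proportion output on one scale.
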