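---
title: "Linking average-based and individual-based change in pre-post designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking average-based and individual-based change in pre-post designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(changelink)
```

## The two views of pre-post change

When the same variable is measured in the same cases before and after an
intervention, the change can be summarized at two levels.

At the **group level** (average-based change), the single-group effect
size used throughout this package is the standardized mean of the
pre-post differences,
$$d = \frac{M_{post} - M_{pre}}{S_{dif}},$$
with $S_{dif}$ the sample standard deviation (denominator $n-1$) of the
difference scores $D_i = post_i - pre_i$. Standardizing by $S_{dif}$
(rather than by $S_{pre}$) makes the statistic sensitive to the pre-post
correlation through the denominator, and — as the calibration study below
shows — makes the link to the individual-level percentage essentially
invariant to that correlation. For a two-group (experimental vs. control)
design the group-level statistic is Hays' $\omega^2$ for the
group $\times$ occasion interaction of the $2 \times 2$ mixed design,
$$\hat\omega^2 = \frac{gl_{AB}(F_{AB}-1)}{gl_{AB}(F_{AB}-1)+N},$$
where $F_{AB}$ is the interaction $F$, $gl_{AB} = 1$, and $N$ is the
total number of *scores* in the design ($N = 4n$ with $n$ cases per
group, two occasions each). For this design the interaction $F$ equals
the squared pooled-variance independent-samples $t$ on the difference
scores, which is how `interaction_omega_squared()` computes it; the test
suite checks the equivalence against a brute-force `aov()` decomposition
on every random instance it draws.

At the **individual level** (individual-based change), each case is
classified as having changed reliably or not. Two standardizations of
$D_i$ are implemented:

* the **SID**, $D_i / S_{dif}$ — whose mean across cases is exactly $d$;
* the **RCI**, $D_i / \sqrt{S^2_{pre}(1-r) + S^2_{post}(1-r)}$ — the
  variant that does not assume equal occasion variances. By default the
  reliability $r$ is the sample pre-post correlation, the choice with the
  lowest false-positive rate; an external estimate can be supplied.

A case counts as a reliable improvement when its index value *strictly
exceeds* the cutoff: 1.645 for the one-tailed rule used in single-group
designs (only improvements are expected), $\pm 1.96$ for the two-tailed
rule used with a control group (worsenings matter when comparing
treatments). Values exactly at the cutoff are not reliable changes. The
percentage of improvements, or the net percentage
$P_{net} = (P^+_{exp} - P^-_{exp}) - (P^+_{ctrl} - P^-_{ctrl})$,
is the individual-based summary. $P_{net}$ is reported unclipped (its
raw range is $[-200, 200]$); *predictions* of percentages are clipped to
$[0, 100]$, and of net percentages to $[-100, 100]$.

Under normality with known unit SD of the differences, the expected
percentage above a cutoff $c$ at effect $\delta$ is
$100\,(1 - \Phi(c - \delta))$ (`analytic_percent_normal()`): 5% at
$\delta = 0$ and about 13% at $\delta = 0.5$ for $c = 1.645$. This serves
as the known-parameter oracle for the Monte-Carlo percentage.

## The synthetic-cohort generator

The calibration study needs paired scores with controlled marginal shape,
pre-post correlation and mean shift. Generation proceeds in three steps:

1. **Marginals.** Two independent vectors are drawn from the Pearson
   distribution system (`rpearson()`) with mean 0, SD 1 and the requested
   skewness $g_1$ and excess kurtosis $g_2$ (normal = 0; the feasibility
   bound $g_2 \ge g_1^2 - 2$ is enforced, and the two-point boundary
   itself is rejected).
2. **Correlation.** The Cholesky factor of the $2\times2$ correlation
   matrix mixes them: $pre = x^{*}$,
   $post^{*} = \rho\,x^{*} + \sqrt{1-\rho^2}\,y^{*}$, so the population
   correlation is exactly $\rho$ for any marginals. For non-normal
   marginals the mixing perturbs the shape of the *post* variable
   somewhat; this drift is accepted without correction — only the
   marginal specification, not the joint shape, is controlled.
3. **Effect injection.** Every post score is shifted by $\delta$ standard
   deviations of the difference scores, so each case experiences a
   different change centred on the designed effect.

### The effect-injection convention

Step 3 admits two readings, and the distinction matters. With unit
occasion variances the *population* SD of the differences is
$\sigma_{dif} = \sqrt{2(1-\rho)}$ (1, 0.775, 0.447 for $\rho$ = 0.5, 0.7,
0.9; `sigma_dif()`), and `inject_effect()` implements the population
shift $\delta\,\sigma_{dif}$. The default used by the simulation
functions, however, is `injection = "sample_sdif"`: the shift is $\delta$
times the *sample* SD of the pre-injection differences. Under this
convention the realized effect is $\delta$ in the sample's own difference
metric — the sample $d$ equals $\delta$ plus a zero-mean disturbance
whose variance does not grow with $\delta$ — and it is the convention
under which the packaged calibration table was produced: with
population-SD injection the sampling noise of $d$ inflates with $\delta$,
visibly attenuating the fitted slope and deflating $R^2$ relative to the
calibration values that sample-SD injection reproduces (the acceptance
checks in `tests/testthat/test-acceptance.R` run at full scale under the
default convention). Both conventions are available on every simulation
entry point.

### Sampling the Pearson system

The Pearson family is selected from the $(g_1, g_2)$ pair through the
roots of the quadratic in the Pearson differential equation
$p'/p = -(c_1+x)/(c_0+c_1x+c_2x^2)$, whose coefficients are fixed by the
first four moments. Types 0 (normal), I/II (four-parameter beta), III
(gamma), V (inverse gamma), VI (beta prime) and VII (scaled Student $t$)
are sampled in closed form through `rbeta()`, `rgamma()` and `rt()`
after mapping the density exponents; negative skewness is handled by
mirroring. Type IV, which has no closed-form representative among the
standard generators, is sampled by inverting its closed-form log-density
numerically: the density is tabulated on 20,001 equally spaced points
over an adaptive range (grown outward from the mode until the density has
fallen by 46 log units), the CDF accumulated by the trapezoid rule, and
draws obtained by interpolating uniform variates through the table, which
is cached per shape. The grid is fine enough that the first four moments
of the tabulated distribution agree with the target to well below any
Monte-Carlo tolerance used here.

Correctness is arbitrated by moment recovery, in two layers. The exact
layer integrates the Pearson ODE density independently (partial-fraction
closed forms plus adaptive quadrature, in the test helpers) and checks
that the implied population mean, SD, skewness and kurtosis equal the
request for every study shape. The sampled layer checks sample moments at
$n = 10^6$ — but only where that estimator is informative: for the
heavy-tailed study shapes ($g_2 = 9$ with tail $\sim x^{-9}$, $g_2 = 18$
with tail $\sim x^{-7.3}$) the eighth moment is infinite and the sample
kurtosis at $n = 10^6$ has sampling error of order $\pm 2$, so for those
shapes the suite instead compares sample quantiles with the
independently integrated CDF (root-$n$ consistent and tight). Pairs on
singular boundaries of the moment plane ($10\beta_2 - 12\beta_1 - 18 =
0$, e.g. the uniform's moment pair) are rejected with an explicit error
rather than approximated.

## The calibration study

`study_config()` defaults to the full factorial grid: 13 effect sizes
$\delta \in \{0, 0.3, \ldots, 3.6\}$ (chosen so the percentage of
changes spans 0–100%), per-group sizes $n \in \{25, 50, 100\}$,
correlations $\rho \in \{0.5, 0.7, 0.9\}$ (repeated-measures correlations
below 0.5 are rare in practice) and seven marginal shapes from extreme
negative to extreme positive skewness
($(g_1, g_2) \in \{(-3,18), (-2,9), (-1,2), (0,0), (1,2), (2,9),
(3,18)\}$) — 819 conditions, 500 samples each. A **condition row** fixes
(shape, $\rho$, $n$, design) and sweeps all 13 deltas, giving
$13 \times 500 = 6{,}500$ (effect size, percentage) pairs per row;
`run_condition()` computes them and fits all four link families to the
pooled cloud, mirroring the per-row scatterplots. `run_study()` iterates
the 63 rows per design and assembles the $R^2$ and linear-coefficient
tables; `summarize_tables()` writes them as CSV/JSON.

Seeding: a master seed is split into per-row substreams by a fixed
affine map modulo $2^{31}-19$, so rows are reproducible individually and
invariant to execution order. Degenerate draws (zero variance of the
differences — probability zero under continuous generation, guarded
anyway) are redrawn once and counted; a row that fails entirely is
recorded with a warning and the study continues.

## Link functions and conversion

Within a condition row the percentage is regressed on the effect size.
The polynomial families (linear, quadratic, cubic) are ordinary least
squares with classical standard errors; the logistic family is
$ibc = 100/(1+e^{-(b_0+b_1\,abc)})$ — a two-parameter curve with fixed
asymptotes 0 and 100, the simplest bounded-response reading of
"logistic" — fit by nonlinear least squares (`minpack.lm::nlsLM`) from a
logit-transform start plus a small multi-start grid, keeping the best
converged fit and failing loudly (with data diagnostics) if none
converges. Because the parameterization of the historical logistic fits
is not recorded, its $R^2$ is reported for comparison only; nothing else
depends on it — and note that with fixed 0/100 asymptotes this family can
fit the single-group cloud substantially better than older
curve-estimation defaults. $R^2$ is always $1 - SSE/SST$ on the raw
percentage scale, the same formula for every family, so families are
directly comparable; for nested polynomials it is non-decreasing in the
degree by construction. Constant responses ($SST = 0$) and degenerate
designs (all effect sizes equal) are errors, not NaNs.

`convert_effect_to_percentage()` applies the packaged linear coefficients
(`link_coefficients()`; produced at $n = 25$ with 500 replicates, the
noisiest and therefore most conservative calibration, and regenerable via
`run_study()`) after selecting the nearest condition row by shape and
correlation — nearest in squared distance over skewness, kurtosis (scaled
by 6 so that one skewness unit weighs as much as six kurtosis units,
their approximate trade-off along the study shapes) and $\rho$. Because
the coefficients vary little across conditions, selecting a neighbouring
row moves the estimate only slightly. Predictions are clipped to the
response range.

## Applied use

`read_score_table()` reads per-case CSV data (`case_id`, `pre`, `post`,
optional `group`; comma-separated, decimal point, header required; rows
with missing scores are dropped with a warning, duplicated ids are
errors). `analyze_change()` then implements the recommended reporting
sequence — per-case index values and labels, the aggregated (net)
percentage, and the classical effect size alongside — choosing the
design, cutoff and tails from the data unless overridden (two distinct
group labels trigger the control-group path; the lexicographically first
label is taken as control unless `experimental=` says otherwise).

## Problem sizes used by the tests

The acceptance layer of the test suite runs three condition rows at full
scale (6,500 samples each: single-group and control-group normal rows at
$\rho = 0.5$, and the single-group normal row at $\rho = 0.7$) and
checks the fitted slope, $R^2$ and the prediction at $d = 1$ against the
packaged calibration values at the precision those values are quoted to.
Everything else runs at smoke scale (tens of replicates, $n \le 25$) or
against exact oracles; generator checks use $10^5$–$10^6$ draws. The
whole suite completes in well under a minute on one CPU; the full
819-condition study is not exercised by the tests but completes in tens
of minutes via `run_study()`.

## Known limitations

* Pre and post share one marginal shape and unit variance; only the
  center moves. Interventions that change spread or shape between
  occasions are outside the calibrated conditions.
* Measurement error is not modelled; like any attenuating factor it
  lowers both the effect size and the percentage of reliable changes,
  and the link coefficients are calibrated on error-free scores.
* The Cholesky mix controls the marginals and the correlation, not the
  full joint distribution; with non-normal shapes the implied joint is
  one particular choice among many with the same margins.
* The packaged coefficients come from $n = 25$ rows; the link's mean is
  stable across $n$ (larger $n$ only tightens the scatter), but the
  $R^2$ values quoted are specific to $n = 25$.
* Regression-based individual change indices and external-anchor
  (clinically-important-difference) methods are out of scope.
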