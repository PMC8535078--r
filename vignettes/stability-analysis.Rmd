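---
title: "Joint-regression stability analysis of multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-regression stability analysis of multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oatmet)
```

## The problem

A multi-environment trial (MET) grows a set of crop varieties in replicated
randomized-block plots across a series of environments — site by
harvest-year combinations. Breeders and end users need to know not only a
variety's mean performance but its *stability*: how strongly each trait
responds when the environment improves or deteriorates. For milling oats
this matters for yield and equally for the quality traits the mill pays
for — groat content, hullability, hectoliter weight, grain size and shape,
and composition (protein, oil, beta-glucan).

`oatmet` implements the full analysis chain: trait derivation from raw
measurements, variety-by-environment cell means, a modified joint
regression for stability, seasonal weather covariates and trait-weather
correlation tables, and a principal-component trait biplot with
per-variety convex hulls. A seeded simulator generates MET data with
exactly the structure the model assumes, so every statistical property the
package claims is checked by simulation in its test suite.

## The model

The core is the Finlay–Wilkinson-type bilinear model on variety-by-
environment cell means $y_{ij}$:

$$y_{ij} = V_i + b_i E_j + \varepsilon_{ij},$$

with variety means $V_i$ ($i = 1,\dots,g$), sensitivities $b_i$, and an
environmental index $E_j$ ($j = 1,\dots,e$). $b_i > 1$ marks a variety
that exaggerates environmental differences (sensitive), $b_i < 1$ one that
buffers them (stable).

Classical joint regression fixes $E_j$ at the observed environment means
and regresses each variety on them; because each variety's data then
appear on both sides of the regression, the slopes are biased, especially
for small $g$. The *modified* form estimates $E_j$ jointly with
$(V_i, b_i)$ as a constrained bilinear least-squares problem. The model is
only identified up to an affine transfer between $V$, $b$ and $E$, so we
impose the standard constraints $\sum_j E_j = 0$ and
$\operatorname{mean}_i(b_i) = 1$.

### Fitting: alternating least squares

`fit_joint_regression()` alternates exact least-squares half-steps:

1. initialise $E_j$ as centred observed environment means, $b_i = 1$;
2. given $E$: per-variety simple regression of $y_{ij}$ on $E_j$ over that
   variety's observed cells gives $(V_i, b_i)$;
3. given $(V, b)$: $E_j = \sum_i b_i (y_{ij} - V_i) / \sum_i b_i^2$ over
   the cells observed in environment $j$;
4. re-identify: absorb $\operatorname{mean}(E)$ into $V$, rescale
   $(b, E) \to (b/c,\, cE)$ with $c = \operatorname{mean}(b)$; this leaves
   every fitted value unchanged.

Each half-step solves its subproblem exactly, so the residual sum of
squares is non-increasing — a property the test suite asserts on the
iteration trace. For complete data the solution is the row-mean vector
plus the rank-1 truncated SVD of the row-centred matrix (rescaled to
mean-1 slopes); the tests use `svd()` directly as an independent oracle
and require agreement to $10^{-8}$.

Missing cells are handled by available-case sums throughout; they reduce
the observation count only. The error degrees of freedom are
$n_{obs} - (2g + e - 2)$: $g$ means, $g$ slopes, $e$ indices, minus the
two identification constraints.

### Numerical choices

* **Convergence.** Iteration stops when the relative RSS change falls
  below `tol` ($10^{-10}$ by default) *and* the largest change in any
  fitted cell falls below `tol`/100 times the data scale. The second
  condition is essential: the RSS is locally quadratic around the optimum,
  so an RSS-only rule can stop while the parameters are still
  $\sim 10^{-6}$ away from the least-squares solution. The alternating
  scheme converges linearly at a rate governed by the gap between the two
  leading singular values of the row-centred matrix, so the iteration cap
  defaults to a generous 2000; hitting it flags (but does not error) the
  fit.
* **Exact fits.** When the pooled residual mean square is numerically zero
  (rank-1 data), F tests are meaningless; the fit carries an `exact_fit`
  flag and tests report $p = 0$ (with a positive effect sum of squares) or
  $p = 1$ (without), rather than dividing by zero.
* **Degenerate index.** If the environment means have no spread, $E$ is
  identically zero and the slopes are undefined; the fitter raises an
  error advising an additive-only model instead of returning noise.
* **Initialisation is deterministic** (no RNG anywhere in the fitter), so
  a fit is exactly reproducible.

### Tests and classification

`slope_heterogeneity_test()` computes
$F = \big[\sum_i (b_i - 1)^2 \sum_{j \in obs(i)} E_j^2 / (g-1)\big] / s^2$
against the pooled residual mean square $s^2$, on $(g-1,\,
\mathrm{df}_{error})$ df — the formal test for genotype-by-environment
interaction of the regression type. `variety_effect_test()` is the
analogous F test on the $V_i$ (weighted by per-variety cell counts).
`classify_stability()` labels a variety sensitive/stable when its slope
differs from 1 by a two-sided t test at $\alpha = 0.05$, and "average"
otherwise.

Standard errors are *conditional on the final $E$* — the classical
joint-regression reporting convention. They ignore the uncertainty in the
estimated indices and are therefore mildly optimistic; this is a
documented approximation, and the null calibration below shows that the
heterogeneity F test nevertheless holds its nominal size at the study's
dimensions ($e \gg g$). The published standard errors for this trial
series came from plot-level data that were never released, so the
package's pooled-residual construction is a design choice, not a
reproduction; with means-only input its absolute values are not comparable
to the published ones.

## Derived grain traits

Deterministic formulas, each a pure vectorised function with domain
checks:

| Function | Formula | Units |
|---|---|---|
| `groat_content()` | $100\,\text{groat}/(\text{initial} - \text{residual})$ | % |
| `hullability()` | $100 - 100\,\text{residual}/\text{initial}$ | % |
| `roundness()` | width / length | ratio in (0, 1] |
| `protein_from_nitrogen()` | $N \times 5.36$ (oat Jones factor) | % |
| `grain_number()` | yield $\times 100$ / TGW | 1000 grains m$^{-2}$ |
| `adjust_yield_moisture()` | yield $(100 - m)/(100 - 15)$ | t ha$^{-1}$ |

The moisture adjustment conserves dry matter; the convention that was
actually used for the published yields is not stated, and dry-matter
conservation is the standard choice. Both ratio traits are invariant to
rescaling all masses, a property tested explicitly. `roundness()` warns
(rather than errors) when width exceeds length, since that almost always
means swapped dimensions.

Recomputing the published derived columns from the published rounded
inputs reproduces roundness within 0.002 in 21 of 22 environments (the
exception deviates by 0.0022) and grain number within 2% in 21 of 22 (the
spring-sown environment deviates by 3.2%): the published derived columns
were evidently computed from unrounded plot data, so input rounding sets
the reproduction floor.

## Weather covariates and trait-weather correlations

`weather_window()` defines a seasonal window (start/end month and day)
anchored to each environment's harvest year. For an autumn-sown crop the
season spans two calendar years, so months from September onward default
to the year *before* harvest ("December to April" means 1 Dec of the
pre-harvest year through 30 Apr of the harvest year); explicit year
offsets can override this. Aggregation is the cumulative sum for rainfall
and radiation and the mean of the daily midpoint $(t_{min}+t_{max})/2$ for
temperature — the daily-mean definition is a convention choice, stated
here because recorded data rarely include true daily means. A window with
more than 10% of its days missing yields a missing covariate with a
warning rather than a silently truncated sum.

`correlation_table()` computes Pearson correlations between per-
environment trait means and covariates with *pairwise* deletion: a trait
missing in some environments loses only those rows, so different cells of
the same table can carry different degrees of freedom (in the bundled
trial: 19 for complete traits, 17 for hectoliter weight, which was not
measured in two environments). Environment exclusions (the spring-sown
trial) are metadata flags applied at table time, not hard-coded. P-values
come from the exact t transform $t = r\sqrt{df/(1-r^2)}$, two-sided, with
stars at 0.05/0.01/0.001.

## The biplot

`trait_biplot()` uses correlation-matrix PCA — columns centred and scaled
to unit variance — because the traits carry heterogeneous units (t/ha, %,
mm, g); with unscaled PCA the loadings would simply rank trait variances.
Scores and loadings split the singular values symmetrically by default
($\alpha = 0.5$), with row-metric ($\alpha = 1$) and column-metric
($\alpha = 0$) options; the rank-2 reconstruction is invariant to
$\alpha$. Missing entries are mean-imputed per trait with a reported
count (or rows dropped on request); constant columns are dropped with a
warning. Axis signs are fixed by making the largest-magnitude loading on
each axis positive, so results do not depend on the LAPACK sign
convention. The cosine between two trait loading vectors tracks the sign
of their correlation *when the first two components dominate*; this is
asserted in tests only on two-component-dominated fixtures, because it is
not a theorem for general data.

`convex_hulls()` wraps each group's scores in its minimal convex polygon
(vertices counter-clockwise, shoelace area). In a variety-by-environment
biplot, hull area per variety summarises how far that variety's trait
profile travels across environments — a visual complement to the
sensitivity slopes.

## The synthetic generator

`synthetic_truth()` + `simulate_met()` invert the analysis model exactly:
$y_{ijk} = \mu + V_i + b_i E_j + \varepsilon_{ijk}$ with iid Gaussian plot
noise, optional whole-cell deletion, and exact identification
($\operatorname{mean}(b) = 1$, $\sum E = 0$, $\operatorname{sd}(E) =
\sigma_E$ exactly, by re-centring/rescaling after drawing). Defaults are
fixed at the bundled study's design and scale: $g = 4$, $e = 22$, $r = 3$;
$\mu = 8.16$ t/ha and $\sigma_E = 1.5$ t/ha (the mean and spread of the
bundled per-environment yields); $\sigma_V = 0.12$ (the four published
variety yield means span only ~0.3 t/ha); slope spread 0.15 (the published
yield slopes span 0.84–1.15); plot noise $\sigma_\varepsilon = 0.5$ t/ha,
a ~6% CV typical of well-run cereal variety trials. Calibration
experiments in the tests use the noise ratio
$\sigma_\varepsilon = 0.3\,\sigma_E$.

Cell deletion is Bernoulli per cell, then minimally repaired so every
environment keeps $\ge 2$ observed varieties and every variety $\ge 3$
environments — the generated data satisfy the fitter's preconditions *by
construction*, which keeps high-missingness property tests meaningful.

`simulate_weather()` constructs each environment's windowed aggregate as
$A_j = m + s\,(\rho\, z(E_j) + \sqrt{1-\rho^2}\,\zeta_j)$ and spreads it
uniformly over the window's days, so the covariate-index correlation
converges to $\rho$ and is exactly affine at $|\rho| = 1$. Rainfall is
clamped at zero at the aggregate level (irrelevant at the default
location/scale) and $t_{min} \le t_{max}$ holds by construction.

All randomness flows from one root seed with fixed stream offsets (effect
draws, replicate noise, missingness, weather), so sub-experiments are
independently reproducible and a simulation is bit-identical across runs.

**What the generator does and does not emulate.** It reproduces the
randomized-block mean structure, the bilinear interaction, MCAR cell
missingness and a controllable trait-weather linkage. It does *not*
simulate spatial field trend, block effects, non-Gaussian or
heteroscedastic errors, genetic correlation between traits beyond a
shared environmental index, or realistic daily weather (occurrence
processes, seasonality). Passing recovery and calibration tests therefore
demonstrates correctness of the estimator under the model's own
assumptions — not robustness to the field realities the model ignores.

## Problem sizes and runtime conventions

The simulation studies shipped in the tests and analysis scripts use 200
synthetic trials for slope-recovery RMSE and 1000 for the null
calibration of the heterogeneity test, both at the study's own
$4 \times 22 \times 3$ dimensions — sizes chosen so Monte-Carlo error is
well below the quantities being checked (the null rejection rate is
asserted within $0.05 \pm 0.02$, whose binomial SE at $n = 1000$ is
0.007). A single fit at these dimensions takes a few milliseconds.

## Known limitations

* Standard errors (and hence the stability classification) are
  conditional on the estimated $E$; for $g$ as small as 4 the slope tests
  should be read alongside the heterogeneity F test rather than in
  isolation.
* The weighting scheme for *unbalanced* data (unequal replicate counts
  behind cell means) treats all cell means equally; replicate counts are
  carried but not used as weights.
* With means-only input (as in the bundled trial) the pooled residual
  mean square absorbs both plot error and any lack of fit of the bilinear
  model; published standard errors computed from plot data are not
  recoverable.
* The biplot's angle-correlation reading degrades as the variance share
  of the first two components falls; the variance fractions are part of
  the object so that readers can judge this.
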