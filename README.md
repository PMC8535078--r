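# oatmet

Genotype-by-environment stability analysis for multi-environment variety
trials, built around the quality and yield traits of milling oats.

## The problem

When a crop variety is grown across many environments (site ×
harvest-year combinations), its traits respond to the environment to
different degrees. Breeders, millers and agronomists need to separate a
variety's *mean* performance from its *sensitivity*: does it exaggerate
environmental differences, or buffer them? For milling oats this applies
not only to yield but to the traits the mill pays for — groat content,
hullability, hectoliter weight, grain size and shape, protein, oil and
β-glucan.

`oatmet` implements the modified joint-regression (Finlay–Wilkinson-type)
stability model on variety-by-environment cell means

y<sub>ij</sub> = V<sub>i</sub> + b<sub>i</sub> E<sub>j</sub> + ε<sub>ij</sub>

where V<sub>i</sub> is the mean of variety *i*, E<sub>j</sub> a latent
environmental index, and b<sub>i</sub> the variety's sensitivity
(b > 1 sensitive, b < 1 stable). The "modified" form estimates
E<sub>j</sub> *jointly* with the slopes by alternating least squares,
under the identification constraints Σ E<sub>j</sub> = 0 and
mean(b<sub>i</sub>) = 1 — removing the bias of regressing each variety on
environment means that contain its own data. For complete data the
solution equals the rank-1 SVD of the row-centred mean matrix, which the
test suite uses as an independent oracle.

Around the core model the package provides:

* **Trait derivation** — groat content, hullability, roundness
  (width/length), protein from nitrogen (× 5.36), grain number from yield
  and TGW, moisture-standardised yield.
* **MET data handling** — long-format replicate records with explicit
  missingness, cell/environment/variety means, validated environment
  metadata.
* **Weather covariates** — seasonal windows (e.g. "December–April
  rainfall") anchored to each environment's harvest year, plus Pearson
  trait–weather correlation grids with pairwise deletion and
  significance stars.
* **Trait biplots** — correlation-matrix PCA with symmetric/row/column
  scaling and per-variety convex hulls.
* **A seeded simulator** of randomized-block MET data (and linked
  weather) with exactly the model's structure, used for the package's
  parameter-recovery and calibration tests.

The summary tables of a published UK winter oat trial network (4
varieties × 22 environments, harvests 2011–2014) are bundled via
`oat_trial()` as worked fixtures.

## Worked example

Simulate a 4 × 22 × 3 trial with unequal sensitivities, fit the model,
and test for genotype-by-environment interaction:

```r
library(oatmet)
sim <- simulate_met(synthetic_truth(seed = 42, sigma_b = 0.25))
fit <- fit_joint_regression(cell_means(sim$met, "yield"))
fit
#> Modified joint regression: trait 'yield' (unspecified)
#>   4 varieties x 22 environments, 88 observed cells
#>   RSS 3.41908 on 60 error df (7 iterations, converged)
#> # A tibble: 4 × 6
#>   variety  mean se_mean sensitivity se_sensitivity stability
#>   <chr>   <dbl>   <dbl>       <dbl>          <dbl> <chr>
#> 1 V1       8.25  0.0509       0.912         0.0345 stable
#> 2 V2       8.06  0.0509       0.869         0.0345 stable
#> 3 V3       8.09  0.0509       1.27          0.0345 sensitive
#> 4 V4       8.31  0.0509       0.949         0.0345 average

slope_heterogeneity_test(fit)
#> F test: slope heterogeneity (all b_i equal)
#>   F(3, 60) = 28.06, p = 1.827e-11
```

The variety means sit near the grand mean of 8.16 t/ha; V3's slope of
1.27 means it gains (and loses) about 27% more than the average variety
as environments improve (or worsen), and the F test confirms the slopes
differ.

Correlate bundled trait means with summer rainfall, excluding the
spring-sown environment:

```r
trial <- oat_trial()
covs <- trial$environments[, c("environment", "rain_jun_jul")]
correlation_table(trial$env_means[, c("environment", "yield",
                                      "hullability", "beta_glucan")],
                  covs, exclude = "8")[, c("trait", "r", "df", "stars")]
#> # A tibble: 3 × 4
#>   trait            r    df stars
#>   <chr>        <dbl> <int> <chr>
#> 1 yield       -0.768    19 ***
#> 2 hullability  0.804    19 ***
#> 3 beta_glucan -0.846    19 ***
```

Wet summers in this series meant lower yield and β-glucan but easier
hull removal.

## Analysis scripts

The `analysis/` directory holds numbered drivers that narrate the full
study and write their tables under `results/`:

1. `01_trial_overview.R` — bundled trial summaries, trait ranges,
   internal-consistency checks.
2. `02_trait_formulas.R` — recomputes the derived-trait columns from the
   published inputs and reports the reproduction deviations.
3. `03_stability_simulation.R` — slope-recovery RMSE (200 trials) and
   null calibration of the heterogeneity test (1000 trials).
4. `04_weather_correlations.R` — full trait × covariate correlation grid
   against the published table.
5. `05_biplot.R` — environment-level and variety-by-environment biplots
   with convex hulls.

Run any of them from the repository root, e.g.
`Rscript analysis/03_stability_simulation.R`.

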