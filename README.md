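# sbaspatial

District-level spatial analysis of health-indicator coverage, built around
the question of where skilled-birth-attendance (SBA) coverage clusters and
what district characteristics move it. The package implements the full
areal-data workflow for epidemiologists and health geographers working with
district percentage indicators:

1. **Contiguity weights** from polygon geometry — queen contiguity
   (boundaries share at least one point) and the stricter shared-border
   variant (a positive-length common segment), with row standardization and
   explicit island handling.
2. **Global spatial autocorrelation** — univariate and bivariate Moran's I
   with permutation pseudo p-values:

   `I = (n / S0) * sum_ij w_ij (x_i - x̄)(x_j - x̄) / sum_i (x_i - x̄)²`

   where `S0 = sum_ij w_ij`. The bivariate form crosses the standardized
   value of one variable with the standardized spatial lag of another.
3. **Local indicators of spatial association (LISA)** —
   `I_i = n (x_i - x̄) / sum_k (x_k - x̄)² * sum_j w_ij (x_j - x̄)`,
   with conditional-permutation inference and the Moran-scatterplot
   four-quadrant classification into hotspots (high-high), coldspots
   (low-low) and spatial outliers (high-low / low-high), exported as
   labelled GeoJSON map layers.
4. **Spatial regression** by maximum likelihood — OLS
   (`y = a + Xb + e`), the spatial lag model (`y = δWy + Xb + e`) and the
   spatial error model (`y = Xb + u`, `u = λWu + e`), compared by AIC
   (`2k − 2·logL`; lower fits best).
5. **Synthetic district scenarios** — lattice polygons, spatially
   autocorrelated percentage covariates from a simultaneous-autoregressive
   process, and outcomes generated under spatial-lag/spatial-error models at
   known parameters, so the whole pipeline is testable without
   access-restricted survey microdata.

I/O covers GeoJSON (RFC 7946), ESRI shapefile, CSV attribute tables and GAL
contiguity files.

## Worked example

The numbered scripts under `analysis/` run the whole study workflow on the
640-district synthetic scenario; each step prints what it found and writes
its tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # lattice + covariates + SEM outcome
Rscript analysis/02_weights.R      # queen contiguity, GAL export
Rscript analysis/03_global_moran.R # "Table 1": global Moran per variable
Rscript analysis/04_lisa.R         # LISA cluster maps + counts
Rscript analysis/05_regression.R   # "Table 2": OLS vs SLM vs SEM by AIC
```

The same computation in a few lines:

```r
library(sbaspatial)
sc <- make_district_scenario("paper_shape", seed = 42)  # 640 districts
W  <- row_standardize(queen_adjacency(sc$frame))

global_moran(W, sc$table[["Delivery conducted by SBA (%)"]])
#> <global_moran> univariate I = 0.5642  pseudo p = 0.001 (999 permutations)
#>   n = 640, E[I] = -0.001565
```

The outcome's Moran's I of 0.56 means strong positive spatial
autocorrelation: districts with high SBA coverage adjoin other high-coverage
districts. The pseudo p of 0.001 is the floor at 999 permutations — no
random reassignment of values to districts came close to the observed
clustering. Fitting and ranking the three regression models
(`analysis/05_regression.R`) prints:

```
model spatial_parameter spatial_estimate log_likelihood     aic  k     r2
  sem            lambda         0.661811       -1972.65 3969.31 12 0.7210
  slm             delta         0.459115       -1983.09 3990.19 12 0.6957
  ols                NA               NA       -2043.22 4108.43 11 0.6146
```

The spatial error model wins on AIC and its `lambda` estimate (0.66) sits
near the generating truth (0.7): the residual spatial structure built into
the data is detected and attributed to the disturbance process, exactly the
model-selection logic used for real district data.

## Layout

- `R/` — package implementation (weights, Moran/LISA, ML spatial
  regression, synthetic scenarios, pipeline orchestration, geo I/O)
- `analysis/` — numbered narrative drivers for the study workflow
- `scripts/acceptance.R` — headline-number reproduction
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `vignettes/district-spatial-analysis.Rmd` — methods notes: model
  assumptions, conventions, numerical choices and limitations
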