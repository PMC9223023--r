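# odrlight

Predicting the municipal **old-age dependency ratio (ODR)** of Chinese
cities from nighttime-light brightness, with spatial-autocorrelation
analysis of the predicted field.

Fine-grained census data below the provincial level are scarce in China,
while DMSP/OLS nighttime-light imagery (integer digital numbers, DN 0–63,
~1 km) is freely available and tracks human activity. `odrlight`
implements the complete workflow for exploiting that link, for
demographers and spatial epidemiologists who need municipal aging
indicators between censuses:

1. **Zonal brightness** — reproject a DN raster to an equal-area grid
   (spherical Albers, cubic resampling), assign cells to
   province/city polygons by cell center, and reduce to the zonal
   `SUM = Σᵢ DNᵢ` and `MEAN = SUM / n` over each zone's effective pixels.
2. **Curve regression** — fit the eleven-member SPSS-style curve
   estimation family (Linear, Logarithmic, Inverse, Quadratic, Cubic,
   Compound, Power, Sigmoid, Growth, Exponential, Logistic) to provincial
   (SUM of DN, ODR) pairs, where `ODR = 100 · P₆₅₊ / P₁₅₋₆₄`, and select
   the best model by mean R² across years. On real data this selects the
   **Sigmoid** form
   `y = exp(b₀ + b₁/x)`,
   which rises with brightness toward the finite ceiling `exp(b₀)`.
3. **Municipal prediction** — apply the selected curve to municipal SUM
   of DN, then filter to large and medium-sized cities
   (ODR ≥ 13.71 after 2-dp rounding, SUM of DN ≥ 115,762).
4. **Spatial structure** — queen-contiguity weights, global Moran's *I*
   (analytic randomization variance and permutation pseudo-*p*), local
   Moran's *Iᵢ* (LISA) with HH/LL/HL/LH quadrants, and Getis-Ord Gi\*
   hot/cold-spot classes at the ±1.96/±2.58 thresholds.
5. **Synthetic data** — lattice zone maps, Poisson DN rasters with
   saturation at DN 63, sigmoid-linked ODR tables with log-scale noise,
   and simultaneous-autoregressive (SAR) fields
   `x = (I − ρW)⁻¹ε` with known ρ, so every stage can be validated
   against ground truth.

All spatial statistics, contiguity construction, and the text-format I/O
(ESRI ASCII grid rasters, GeoJSON polygons, GAL weights) are implemented
in the package; classes are S4 with validity checks and accessors.

## Worked example

A full synthetic run under the default scenario (8×8 city lattice,
64×64 pixels per zone so zonal sums sit on the 1e5 scale of real
municipal sums, sigmoid link with b₀ = 3.019, b₁ = −46,452, log-scale
noise sd 0.05):

```r
library(odrlight)
res <- runPipeline(defaultPipelineConfig(seed = 2, outDir = "run"))
res$comparison$best
#> [1] "Sigmoid"
round(res$comparison$table["Sigmoid", ], 3)
#>          2016  2017  2018  2019  2020  Mean
#> Sigmoid 0.962 0.958 0.953 0.952 0.959 0.957
nrow(res$filtered)
#> [1] 40
round(res$correlations$r, 2)
#>          odr sum_dn mean_dn
#> odr     1.00   0.91    0.91
#> sum_dn  0.91   1.00    1.00
#> mean_dn 0.91   1.00    1.00
res$globalMoranAnalytic
#> Global Moran's I = 0.065 | E[I] = -0.0159 | z = 1.2058
```

The Sigmoid model is correctly selected from its own data (mean
R² ≈ 0.96 across the five synthetic years); 40 of the 64 synthetic
cities pass the large-city filter; the predicted ODR correlates 0.91
with SUM of DN; and because the per-zone brightness intensities are
drawn independently, the global Moran's *I* of the ODR field is small
and not significant (z = 1.21) — turn on `sarRho` in the scenario to
inject genuine spatial structure and watch it become significant.

The published 65-city prediction table ships with the package:

```r
tab <- cityPredictionTable()
fit <- recoverSigmoidFromTwoPoints(c(349408, 17.923), c(265159, 17.182))
max(abs(predictSigmoid(fit, tab$sum_dn) - tab$odr))
#> [1] 0.0008021819
```

Two printed rows determine the whole prediction curve to within a
thousandth of a percentage point on all 65 cities.

## Command-line interface

```sh
Rscript inst/cli/odrlight.R run    --config cfg.yaml --seed 1 --out out/
Rscript inst/cli/odrlight.R synth  --seed 3 --out inputs/
Rscript inst/cli/odrlight.R zonal  --raster r.asc --zones z.geojson --out zonal.csv
Rscript inst/cli/odrlight.R fit    --zonal zonal.csv --odr odr.csv --out fits.csv
Rscript inst/cli/odrlight.R spatial --values odr.csv --gal w.gal --out stats/
```
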