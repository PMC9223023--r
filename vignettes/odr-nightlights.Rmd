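---
title: "Methods: predicting municipal old-age dependency ratios from nighttime lights"
author: "odrlight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting municipal ODR from nighttime lights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odrlight)
```

## The problem and the model

The old-age dependency ratio,
\[
\mathrm{ODR} = 100 \times \frac{P_{65+}}{P_{15\text{--}64}},
\]
is the standard percentage indicator of population aging. Municipal ODR
values are rarely published between censuses, while nighttime-light
imagery is updated annually and correlates strongly with the human and
economic activity that shapes a city's age structure. The package
operationalizes that link in two stages: a brightness summary per zone,
and a curve regression of ODR on brightness calibrated at the
provincial level (where census ODR exists) and applied at the municipal
level (where it often does not).

The brightness summary is the zonal sum of digital numbers,
\(\mathrm{SUM} = \sum_{i=1}^{n} DN_i\), over a zone's *effective
pixels* — all non-nodata cells whose centers fall in the zone polygon,
including zero-DN cells. Zero-DN pixels are genuine observations of
darkness; excluding them would leave the zonal MEAN undefined for dark
zones and bias SUM-per-area comparisons. \(\mathrm{MEAN} =
\mathrm{SUM}/n\) is reported alongside.

The regression stage fits eleven curve-estimation forms. The family and
its fitting conventions follow the SPSS curve-estimation tradition:
forms that are linear in parameters after an x-transform (Linear,
Logarithmic, Inverse, Quadratic, Cubic) are fitted by OLS on the
original y; the intrinsically exponential forms (Compound, Power,
Sigmoid, Growth, Exponential, Logistic) by OLS on a transformed
response, and the selection metric is R² **on the fitting scale**. Both
R² values (fitting scale and original scale) are reported so users can
see when the two disagree. Growth, Compound and Exponential are
reparameterizations of one curve — same regression of \(\ln y\) on
\(x\) — so their R² agree to machine precision, a useful internal
consistency check that the test suite enforces.

The form selected on real data is the Sigmoid,
\[
y = e^{b_0 + b_1/x},
\]
linear in \(1/x\) on the log scale. With \(b_1 < 0\) it increases
monotonically in brightness and saturates at the ceiling
\(e^{b_0}\) — a sensible shape for a bounded demographic ratio driven by
urban development. Because the source study prints predictions but not
coefficients, `recoverSigmoidFromTwoPoints()` solves the two-parameter
form exactly from two printed (SUM, ODR) rows; back-predicting the
remaining rows then validates the reconstruction (the bundled 65-city
table reproduces to < 0.001 percentage points, and the acceptance
script exercises several anchor pairs). The reconstructed coefficients
are approximately \(b_0 = 3.019\), \(b_1 = -4.64 \times 10^4\); they
are treated as a reconstruction, not as published values.

### The Logistic mu convention

The Logistic entry of the family is written
\(y = 1/(1/\mu + b_0 b_1^x)\) with \(\mu\) defined as **the mean of
x**. That differs from the conventional use of an upper-bound
saturation parameter, but it is implemented as written because it is
the documented convention of this family; a
`logisticMuMode = "fixed_bound"` switch restores the conventional
behavior for users who want a true ceiling. With \(\mu = \bar x\) on
the SUM-of-DN scale (1e5), \(1/\mu\) is tiny and the fitted curve is
nearly indistinguishable from the Compound family — consistent with the
identical R² columns those four models produce on real data.

### The large-city filter

Municipal records are filtered by ODR ≥ 13.71 **after rounding the ODR
to two decimals** and SUM of DN ≥ 115,762. The rounding rule is
deliberate: published cutoffs are printed at two decimals, and a city
at 13.706 belongs above a 13.71 cutoff only under that convention. The
filter is exact and order-stable (output sorted by ODR descending).

## Spatial statistics

Spatial structure of the municipal ODR field is summarized by three
statistics under queen-contiguity weights (two zones are neighbors iff
their polygons share at least one boundary point):

* **Global Moran's I**
  \(I = \frac{n}{\sum_{ij} w_{ij}} \cdot
  \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}\), \(z_i = x_i - \bar x\),
  with expectation \(-1/(n-1)\) under the null of no autocorrelation.
* **Local Moran's Iᵢ (LISA)**
  \(I_i = \frac{n\, z_i \sum_j w_{ij} z_j}{\sum_k z_k^2}\), labeled by
  the quadrant of \((z_i, \sum_j w_{ij} z_j)\): HH and LL mark
  clusters, HL/LH spatial outliers. Under row-standardized weights
  \(\sum_i I_i / n\) equals the global I exactly (enforced to 1e-12 in
  tests).
* **Getis-Ord Gi\***, the self-inclusive local concentration z
  statistic with binary weights and \(S\) the divisor-n standard
  deviation; hot/cold classes use the ±1.96 and ±2.58 thresholds
  (boundaries inclusive: \(|z| \ge 1.96 \Rightarrow p \le 0.05\)).

One deliberate correction: a common rendering of the LISA test statistic
states \(E(I_i) = +1/(n-1)\). A positive expectation contradicts the
null of no autocorrelation (the mean of the permutation distribution is
negative), so the package uses the standard \(E(I_i) = -1/(n-1)\) and
documents the discrepancy here.

**Inference.** The global statistic carries both the analytic
Cliff–Ord randomization variance (the style behind published z values
such as 13.53) and a permutation distribution: pseudo-p =
(1 + #{permutations at least as extreme}) / (1 + nPerm), two-sided
around \(E(I)\), default 999 permutations and a user seed. Local
statistics use conditional permutation (the other n−1 values
reassigned to the neighbor slots), which conditions correctly on
\(z_i\). Since the analytic and permutation routes answer the same
question, both are reported for the global statistic rather than
choosing one.

**Standardization defaults** follow the conventions of the exploratory
spatial-analysis software this workflow mirrors: row-standardized
weights for global and local Moran, binary self-inclusive weights for
Gi\*; both are configurable.

**Islands** (zones with no queen neighbor — real coastal cases exist,
e.g. island municipalities) have an undefined spatial lag. They are
kept in the weights object, flagged, and excluded from local statistics
explicitly; silently zero-filling their lag would bias every labeled
cluster they touch. No artificial bridging of islands is attempted.

## Raster preprocessing choices

* **Projection**: a fixed China-extent spherical Albers equal-area
  conic (central meridian 105°E, standard parallels 25°N/47°N) on an
  authalic sphere; configurable via the CRS label. Equal-area matters
  because SUM of DN is an area-extensive quantity.
* **Resampling**: cubic convolution (Keys kernel, a = −0.5) for
  continuous imagery, at 1 km by convention. The cubic kernel can
  overshoot, so outputs are clamped back to [0, 63] but kept
  fractional: rounding would perturb zonal sums, and the integer-DN
  invariant is an acquisition property, not a post-processing one
  (`integerDN` tracks which regime a raster is in).
* **Nodata in interpolation**: a target cell is nodata iff its nearest
  source cell is nodata; otherwise nodata neighbors are dropped from
  the 4×4 (or 2×2) stencil and the kernel weights renormalized. On
  nodata-free interiors this is exactly the textbook convolution, which
  is what the test-suite oracle checks.
* **Cell assignment**: center-point containment, with boundary ties
  resolved to the first zone in ID-sorted order — deterministic and
  independent of feature order in the input file.
* **Raster/ODR vintages** are treated as free metadata: the workflow
  does not attempt temporal alignment between the imagery year and the
  census year, which is a modeling decision for the user.

## The synthetic scenario

The generators produce every input the pipeline consumes, with known
truth:

* `generateLatticeZones()` — square-city lattices whose queen adjacency
  is known in closed form (corners 3, edges 5, interior 8).
* `generateDnRaster()` — per-zone Poisson DN, clipped at 63. Poisson
  (not Gaussian) respects integer DN; clipping mimics sensor
  saturation. Note the clipped-Poisson mean at intensity 63 is ≈ 59.8,
  not 63 — the saturation test compares against the closed-form clipped
  mean.
* `generateSigmoidOdr()` — \(\mathrm{odr}_i = e^{b_0 + b_1/x_i +
  \varepsilon_i}\), \(\varepsilon_i \sim N(0, \sigma^2)\). Noise on the
  log scale makes log-linearized OLS the correctly specified estimator,
  so parameter-recovery tests are sharp (exact at σ = 0, unbiased under
  noise).
* `generateSarField()` — \(x = (I - \rho W)^{-1}\varepsilon\) with
  row-standardized W: a field whose spatial dependence is controlled by
  a single parameter, used to verify detection power (ρ = 0.7 on a
  10×10 lattice) and test size (ρ = 0).

The default pipeline scenario uses an 8×8 lattice with 64×64 pixels per
zone so zonal sums land on the 1e5 scale of real municipal sums, the
reconstructed sigmoid coefficients (b₀ = 3.019, b₁ = −46,452), log-noise
sd 0.05, and intensities spanning most of the DN range — values chosen
once to mirror the real study conditions. Simulation-based tests use 31
units per year (the provincial sample size), 10 years, 100–200
replicates, and 999 permutations for power studies; these sizes give
Monte-Carlo error comfortably below the margins being tested.

**What the synthetic data do not emulate**: sensor geolocation error,
gas flares, inter-annual/inter-satellite calibration drift, irregular
real-world polygon shapes, and the spatial correlation of brightness
*between* zones (intensities are drawn independently unless a SAR field
is injected). Passing tests therefore demonstrate correctness of the
algorithms and estimators under the stated model, not the empirical
validity of the brightness–ODR link on any particular real dataset.

## Numerical details and degenerate inputs

* Curve fits use QR decomposition; rank-deficient designs raise a fit
  error rather than returning aliased coefficients. Domain violations
  (nonpositive y for log models, x = 0 for inverse forms) are reported
  with the offending point indices.
* Model-selection ties break toward fewer parameters, then a fixed
  model-name order, so results are reproducible across platforms.
* Constant fields are refused by all three spatial statistics
  (zero-variance error), and a Gi\* neighborhood that spans the entire
  dataset has an undefined denominator and yields NA.
* Boundary significance is inclusive (z = 1.96 is p ≤ 0.05), matching
  the stated decision rule.
* Identity resampling (same grid, nearest) is bit-exact; all
  determinism guarantees are "same config + same seed ⇒ byte-identical
  outputs", which the pipeline test enforces on every artifact file.

## Known limitations

* The two-level zone nesting (province/city) is positional metadata; no
  containment topology is checked beyond the additivity property tested
  on exact partitions.
* The analytic randomization variance of the global Moran needs n ≥ 4;
  below that only the bare statistic and permutation inference exist.
* The Albers implementation is spherical; ellipsoidal offsets (~0.1%)
  are irrelevant for zonal DN sums at 1 km but would matter for survey
  geodesy, which is out of scope.
* Queen contiguity uses an absolute coordinate tolerance (1e-9 map
  units) for boundary sharing; inputs digitized with larger gaps
  between intended neighbors need pre-snapping.
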