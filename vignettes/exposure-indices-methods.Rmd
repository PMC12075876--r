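---
title: "Methods: census-tract spatial indices of exposure to swine farming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: census-tract spatial indices of exposure to swine farming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swinexpo)
```

## The problem

Communities living near concentrated animal feeding operations (CAFOs) —
here, permitted swine farms with liquid waste systems and open manure
lagoons — face potential exposure to odor, airborne pollutants and
water-quality impacts. How much exposure a census tract faces depends
heavily on how "exposure" is defined. `swinexpo` implements three
tract-level definitions and the machinery to compare them, both with each
other and with generalized vulnerability rankings (CDC-SVI/EJI-style
percentile ranks, consumed as given):

* **Index 1 (buffer count):** the number of unique addresses in the tract
  within one mile of any swine farm. Proximity as exposure.
* **Index 2 (co-kriging):** a continuous surface co-kriged from the natural
  log of permitted head count (primary variable) and the manure-lagoon
  count (secondary), summarised per tract by its zonal *maximum*
  (worst-case) and normalised to percent of the total across tracts.
  Clustering of large farms as exposure.
* **Index 3 (density):** permitted head per square mile of tract land
  area. Animal pressure as exposure.

All geometry is planar, in metres, in a projected CRS the user supplies;
the package performs no reprojection. One mile is 1,609.344 m and one
square mile 2,589,988.110336 m² exactly.

## Index 1: the buffer count

An address qualifies if its Euclidean distance to the *nearest* farm is at
most the radius (inclusive at exactly one mile), and it is counted once no
matter how many farms are in range. A uniform-grid spatial index with cell
size equal to the radius restricts each address's search to a 3 × 3 cell
neighbourhood; the contract is metric-exact and the test suite checks
equality with an exhaustive distance scan.

The per-tract attribution is genuinely ambiguous: "addresses within one
mile of any farm *in the census tract*" can attach the buffer either to the
address's tract or to the farm's. Both readings are implemented behind
`buffer_config(assignment =)`; `address_tract` is the default because the
index is mapped per residential tract. The two modes differ only for
farms/addresses within a mile of a tract border — the edge effect inherent
to buffer counting under the modifiable areal unit problem.

## Index 2: ordinary co-kriging under an LMC

Both variables live on the same farm locations. The empirical
cross-semivariogram on distance bins is

$$\hat\gamma_{uv}(h) = \frac{1}{2N(h)} \sum_{d_{ij} \in \text{bin}(h)}
  (z_u(s_i) - z_u(s_j))(z_v(s_i) - z_v(s_j)),$$

with the direct semivariograms as the \(u = v\) cases. Empty bins are
flagged, never interpolated. A valid bivariate model is enforced through a
**linear model of coregionalization**: every component is a weighted sum of
shared structures \(\gamma_{uv}(h) = \sum_k b^{(k)}_{uv} g_k(h)\) — by
default a nugget plus one spherical structure whose range is pre-fitted
from the primary direct semivariogram. Each 2 × 2 coefficient matrix
\(B_k\) is estimated by weighted least squares (pair-count weights
\(N(h)\)) and projected onto the positive-semidefinite cone by eigenvalue
clipping with re-symmetrisation, which guarantees
\(|b_{12}| \le \sqrt{b_{11} b_{22}}\) per structure and a solvable kriging
system.

Single-variogram fitting (`fit_variogram`) is WLS over nugget, partial sill
and range: conditional on the range the problem is linear in the sills
(with nonnegativity by clipped re-fit), so the optimiser is a deterministic
48-point multistart over the range followed by golden-section refinement.
Exponential and Gaussian families use the practical-range convention
(95 % of the sill at the stated range); the spherical family reaches its
sill exactly at the range.

Prediction is **ordinary co-kriging** of the primary variable: the linear
system stacks the semivariogram blocks \(\Gamma_{11}, \Gamma_{12},
\Gamma_{22}\) with two unbiasedness constraints — primary weights sum to 1,
secondary weights to 0 — via Lagrange multipliers. The prediction variance
is \(\sum_i \lambda_{1i}\gamma_{11}(s_i, s_0) + \sum_j
\lambda_{2j}\gamma_{12}(s_j, s_0) + \mu_1\), clipped to zero below
\(-10^{-9}\). Nugget-free models interpolate exactly at data sites with
zero variance; tests assert this to \(10^{-8}\), along with agreement with
an independently assembled dense solve.

Numerical choices worth knowing:

* Distances are computed from coordinate differences so that coincident
  points have an *exactly* zero distance — otherwise the nugget
  discontinuity would fire at a data point's own location.
* Exactly coincident duplicate data points are averaged (with a warning)
  before the solve; if the system is still singular a tiny diagonal
  regularisation (\(10^{-10}\) of the mean absolute entry) is attempted
  once, and failure names the offending points.
* With a global neighbourhood (`neighborhood = 0`, the default up to a few
  hundred farms) the left-hand side is factorised once and all grid cells
  are solved as one batched right-hand side, which makes the full surface
  essentially one `solve()` call.
* Grid cell centres sit on the absolute lattice `grid_cell * Z`, so halving
  the cell size reproduces every coarse centre exactly (tested nesting
  property).

The zonal statistic is the maximum over cell centres falling in the tract
(partition tie-break: lexicographically smallest tract id). A tract smaller
than one grid cell falls back to a single prediction at its centroid, with
a warning. The percent normalisation \(p_i = 100\, m_i / \sum_j m_j\) sums
to 100 within \(10^{-9}\). Because the index is a *percent of total*, the
choice of log base in the primary variable only rescales the surface and
largely cancels in the normalisation; natural log is used.

## Index 3: head density

Farms are atoms at their permit point: the tract's permitted head total
(point-in-polygon, boundary points assigned by the partition convention)
divided by land area in square miles. The conservation identity
\(\sum_t \text{density}_t \cdot \text{area}_t = \) total head of contained
farms holds exactly in integer head counts and is asserted in the tests.
Land area (not total area) is the denominator, consistent with the
land-area-based urban rule.

## Urban classification and the correlation report

A tract is urban iff at least half its land area lies within the union of
city-limit polygons (inclusive at exactly 50 %). For convex,
non-overlapping city polygons — what the synthetic generator produces — the
fractions are exact Sutherland–Hodgman clip areas summed over polygons; any
non-convex city polygon switches to a deterministic quasi-Monte-Carlo
fraction (10,000 Halton points, bases 2 and 3), accurate to a few parts per
thousand against a rasterisation oracle.

Spearman correlations use average ranks for ties and pairwise deletion of
missing rankings (the public SVI/EJI rankings contain null tracts);
`rho` is the Pearson correlation of the rank vectors. Fewer than three
complete pairs, or zero rank variance, yields a flagged undefined result —
never a silent 0. The report covers all ten unordered pairs among
{idx1, idx2, idx3, svi, eji} in three strata (all/urban/rural), stores full
precision alongside a one-decimal display rounding (half away from zero),
retains pairs with \(|\rho| \ge 0.1\) for the narrative, and flags pairs
whose rounded value differs between urban and rural. No p-values are
reported — `n_pairs` is printed so users can add inference.

Map classes are geometric intervals with a dedicated zero class: with
\(r = (v_{\max}/v_{\min})^{1/k}\), class \(j\) covers
\((v_{\min} r^{j-1}, v_{\min} r^{j}]\), upper-inclusive. This is a plain
multiplicative progression — a deliberate, documented departure from
proprietary GIS "geometric interval" optimisers.

## The synthetic study region

The generator plants the statistical structure the analysis assumes, so
every stage is testable without downloads:

* **Region:** an `n_x × n_y` grid of square tracts (default 10 × 10 of
  4-mile sides). A contiguous block of `round(urban_fraction * n)` tracts
  is urban, each fully covered by a city-limit rectangle — so the ≥ 50 %
  rule reproduces the planted labels exactly.
* **Farms:** tract chosen with rural:urban intensity ratio (default 4,
  matching the farms-per-tract ratio implied by published state-level
  urban/rural farm counts), uniform location within the tract. Permitted
  head is a rounded log-normal, median 3,500 (`meanlog = log(3500)`,
  `sdlog = 0.9`), clipped to [18, 64,680]; the lagoon count is Poisson with
  mean `0.3 · log(head)` clipped to [0, 13], which plants the
  cross-correlation the LMC estimates.
* **Addresses:** a Thomas-style clustered process stratified by urbanicity;
  each address draws its stratum (urban with probability `urban_share`,
  default 0.8), a cluster centre of that stratum, and a Gaussian offset
  (sd 800 m) resampled until the point lands in the stratum — so the
  expected urban share is exactly `urban_share`.
* **Vulnerability:** one shared Gaussian factor with loading λ plus
  idiosyncratic noise per ranking; the SVI latent additionally gets
  `rural_svi_shift` (default 0.5) in rural tracts. Ranks are percentile
  transforms `(rank − 0.5)/n`; a small fraction (default 1 %) is set
  missing per variable. The default loading λ = 0.72 was calibrated by the
  package's own simulation oracle (`calibrate_latent_corr`) to a Spearman
  SVI–EJI association near 0.5; the bivariate-normal identity
  \(\rho_S = (6/\pi)\arcsin(r/2)\) with \(r = \lambda^2\) gives the same
  value and is cross-checked in the tests.

One global seed expands to per-stage seeds by a fixed affine rule, so
stages regenerate independently. Identical seeds give byte-identical
GeoJSON.

What the generator does **not** emulate: real road-network address
patterns, tract-size heterogeneity, coastline/irregular tract shapes,
spatially autocorrelated vulnerability beyond the rural shift, and any
particular state's farm geography. Passing tests therefore demonstrate the
*machinery* — oracle-exact geometry and kriging, recoverable planted
structure — not agreement with any published state-level statistics, which
depend on external registries. Correlations among the indices on the
default scene are emergent outputs, not calibrated quantities.

## Validation design and problem sizes

The test suite checks, at these sizes (chosen to exercise the estimators
well while keeping a full run around half a minute):

* buffer counts vs an exhaustive scan on 50 scenes of 200 farms × 5,000
  addresses;
* co-kriging vs an independent dense solve on 100 random 8-point
  configurations (10⁻⁸), semivariograms vs an all-pairs oracle (10⁻¹²),
  weight-sum constraints at 1,000 prediction points (10⁻⁸);
* spherical-variogram recovery on 50 simulated 400-point Gaussian fields —
  total sill within 25 % and range within 40 % in at least 80 % of fields.
  The simulation domain is 40 km, eight times the true 5-km range, with 14
  lags of 1,250 m: a pilot showed smaller domains (4× the range) simply do
  not contain enough independent range-scale replicates for a stable sill;
* planted rank correlation 0.5 recovered within ±0.1 at n = 400 tracts in
  at least 90 % of 50 seeds;
* exact identities: idx2 percentages sum to 100 (10⁻⁹), density–area
  conservation exact in integer head counts, Spearman ±1 on
  monotone/antitone inputs.

## Worked example

```{r example, eval = FALSE}
library(swinexpo)
res <- run_all(default_config(seed = 1), out_dir = "study")
head(res$exposure, 3)
subset(res$correlations, stratum == "all")
res$report$differs   # pairs whose rounded rho differs urban vs rural
```

## Known limitations

* Planar geometry only; inputs must already be projected (no geodesic
  fallback).
* The LMC default is nugget + one spherical structure; strongly nested or
  anisotropic spatial structure would need explicit `structures`.
* Zonal maxima use cell-centre containment, not area-weighted overlap;
  sliver tracts fall back to a centroid prediction.
* The exact urban fraction requires convex city polygons; concave cities
  use the quasi-Monte-Carlo path (error ≲ 0.005 in the fraction, which can
  matter only for tracts almost exactly half-covered).
* Permitted head counts are regulatory capacity, not live inventory; the
  indices inherit that interpretation.
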