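---
title: "Methods: multi-criteria prioritization of wetland restoration alternatives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-criteria prioritization of wetland restoration alternatives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetsdm)
```

`wetsdm` evaluates a landscape-scale restoration targeting decision by
structured decision making: candidate sites are screened spatially,
measured on criteria that express two fundamental objectives (improve
water quality, enhance climate resilience), ranked under explicit
preference models with sensitivity analysis, and compared regionally with
consequence tables. This vignette documents the models, the choices made
where the methodology was genuinely open, and what the synthetic test
system does and does not demonstrate.

## Spatial screening

The raster route begins from five co-registered grids (elevation, land
use, soils, floodplain, climate flow). Elevations are first conditioned by
inundation-style depression filling: cells inside closed basins rise
exactly to their lowest pour point, never above, so a drained DEM is a
fixed point of the operation. D8 routing then sends each cell to its
steepest-descent neighbor among eight, with drop measured per unit
distance (diagonals count √2 cells). Two determinism rules cover what the
D8 definition leaves open: ties in steepest descent break by the fixed
neighbor order E, SE, S, SW, W, NW, N, NE, and cells on filled flats are
routed by breadth-first assignment toward the flat's spill cell, which
keeps the direction graph acyclic without the epsilon-gradient trick that
would perturb elevations.

Flow accumulation counts each cell's upstream area by topological
ordering; a stream mask takes cells at or above an accumulation threshold
(default 50 cells — a configuration parameter, since no universal
physical threshold exists at desk scale) plus all open-water cells.
Relative elevation subtracts from each cell the elevation of the first
stream cell on its downstream flow path; the ecohydrologically active
area (EHA) is all land within 0.5 m of that reference, with the cutoff
read inclusively (`rel <= 0.5`) so the boundary behavior is exact and
testable. Relative elevation depends only on elevation differences, so
EHA is invariant to uniform datum shifts — one of the suite's property
tests.

Candidate alternatives are 8-connected components of agricultural plus
natural land use (optionally minus prime-farmland and tidal masks) that
reach 121 ha in area and 61 ha of EHA; both thresholds are inclusive and
configurable. Component ids follow scanline order of each component's
first cell, which fixes the labeling. Each alternative's contributing
watershed is the set of cells whose flow path enters it. The seven
criteria then follow by per-cell tallies: TN and TP multiply per-sector
watershed areas by export-coefficient loading rates in kg ha⁻¹ yr⁻¹
(the shipped "2019" and "2025" rate sets are synthetic round numbers of
realistic magnitude; real applications supply their own, converting from
lbs/acre upstream so the core stays unit-clean); AG is the agricultural
share of watershed land area, with open water excluded from the
denominator since it belongs to no load-generating sector; EHA, WS and CF
are patch-cell shares; FP flags floodplain presence inside the patch
itself (not its watershed), matching the criterion's role as an attribute
of the restorable site.

Synthetic runs use 30 m cells rather than fine LiDAR resolution: all
thresholds are stated in hectares, so behavior is scale-consistent, and
grids of a few thousand cells keep the full pipeline under a second.

## Preference scaling

Linear value scaling anchors each criterion at its observed worst
(`x = 0`) and best (`x = 1`); the distance orientation is the exact
complement, so value and distance scalings sum to 1 elementwise — an
identity the tests assert for every scaler. A criterion with no spread
carries no preference information; rather than erroring or biasing one
method, every alternative receives 0.5 and a warning is logged.

TN, TP and CF are heavy-tailed: a very large load in one alternative
should not dominate the analysis. These criteria use a risk-averse
empirical-CDF scale — each measure maps to the share of observations less
than or equal to it, read literally so ties share the ≤-count (not
midranks). The raw step ECDF is used without smoothing or interpolation;
smoothing would add a bandwidth choice without changing ranks, which are
all the downstream methods consume. The distance orientation is defined
as 1 − ECDF so the complement identity and ideal-point semantics carry
over. Concavity of the ECDF (the signature of risk aversion) is checked
with `ecdf_concavity()`: the fraction of non-negative second differences
of the empirical quantile function on a decile grid — a coarse grid,
because adjacent order-statistic spacings are individually noisy — must
exceed one half for the generator's heavy-tailed draws ("largely
concave").

Standardization for the PCA route uses the sample standard deviation
(n − 1). The convention matters only for eigenvalue bookkeeping (the
covariance of standardized data is then exactly the correlation matrix,
so the eigenvalues sum to the number of criteria), not for eigenvector
directions or the resulting selection.

## Ranking and weights

Weights are not elicited per criterion; they follow the two-objective
emphasis scheme. For emphasis proportions 0.60 to 0.90 in steps of 0.05,
the emphasized objective's criteria split the emphasis equally and the
other objective's criteria split the remainder equally — seven iterations
per objective. Two aggregators run on every iteration: the additive value
function V, and the compromise-programming distance D in its power-sum
form `D = Σ w^p x^p` with p = 2 by default. That power-sum form is kept
as the primary definition deliberately; the conventional Lp norm
`(Σ (w x)^p)^(1/p)` is available via `form = "lp"`. Since the norm is the
1/p-th power of the power sum — a monotone map — the two produce
identical rankings for any fixed p, and the option only changes the
reported score scale. At p = 1 both reduce
to 1 − V under the complementary scalings, and the value and distance
rankings coincide exactly — another asserted identity.

Ranks use average ties; any final id ordering breaks ties by ascending
id. Aggregation across a scenario family averages each alternative's
*ranks* over the 14 runs (7 iterations × 2 methods) rather than raw
scores: V and the p-powered D live on incommensurable scales, and ranks
are the common currency. The top 100 mean-ranked alternatives per
objective (boundary ties to the lower id) feed the priority sets.

## PCA route

`pca_first_component()` standardizes the criteria, eigendecomposes their
covariance matrix and scores each alternative on the dominant
eigenvector. Eigenvector sign is arbitrary in the algebra, so the package
fixes it: the TN loading is oriented negative, which makes "lowest Z₁"
select nutrient-heavy (restoration-favorable) alternatives; the applied
sign is recorded in the result. Only the first component is consumed, but
all eigenpairs are returned for diagnostics, and the tests assert
`A v = λ v` to 1e−8, trace conservation, and that `var(Z1) = λ₁`.

## Priority sets and tradeoffs

Highest-priority (`both`) alternatives are those in both objectives' top
sets. Water-quality priorities add the lowest-Z₁ alternatives (minus any
already in `both`); climate-resilience priorities are the remaining
top-climate alternatives. One corner case is underdetermined by that
recipe: an id selected by Z₁ that is also in the climate top set would
fall in two categories. The package keeps the categories a partition by
assigning such ids to the water-quality set — the Z₁ route is a
water-quality instrument — and removing them from climate resilience.

Adjacency expansion (ids neighboring any priority id under the symmetric
adjacency relation) runs *before* the low-elevation exclusion, and the
exclusion applies to expanded ids too, since the elevation constraint
governs everything that would be mapped. The two-foot threshold
(0.6096 m when derived from a DEM) arrives as a boolean attribute so the
set logic stays unit-free. Regions are an input mapping, not an
inference: the original analysis hand-annotated them, and automated
clustering would add assumptions the deliberation never made.

Consequence tables average raw criterion measures over a category's
priority alternatives per region, with three categories: overall (all
priority alternatives), water quality (wq + both), climate resilience
(cr + both); regions without members are omitted rather than zero-filled.
Color coding places each region mean in the upper 20% (favorable), middle
60%, or lower 20% (unfavorable) of its criterion's region means, using
linear-interpolation percentiles with boundary cells assigned to the
adjacent non-middle class. "Preferences were nonlinear" for TN, TP and CF
is operationalized by taking those criteria's percentile cuts on
ECDF-transformed means (against the full alternative table's ECDF),
mirroring the ranking module's scaling; the transform is monotone, so it
changes only the percentile geometry, and a `coding = "raw"` switch is
provided. Cuts are computed within each criterion across regions, not on
the pooled table. The FP column's region mean is a presence proportion
and is coded linearly. Criteria coded identically across regions are
dropped as irrelevant (recorded, and provably unable to affect
dominance — a test asserts the dominance relation is unchanged).
Dominance itself uses only the ordinal codes: region A dominates B when A
is at least as good everywhere and strictly better somewhere. Strict
dominance is irreflexive, antisymmetric and transitive, property-tested
over random coded tables.

## The synthetic study system

`gen_alternatives()` draws TN and TP from lognormal distributions
(meanlog 7.5 / 4.5, sdlog 0.8 — medians near 1800 and 90 kg/yr, plausible
magnitudes for coastal-plain watershed loads) and the percent criteria
from scaled Betas, with CF right-skewed (shape 1.2, 4) so that, like TN
and TP, its ECDF is largely concave; AG is agriculture-dominant
(shape 4, 2, mean ≈ 67%). Floodplain presence is Bernoulli(0.5) and the
low-elevation flag Bernoulli(0.1). These parameters are free choices of
realistic shape — no distributional summaries of the original criteria
exist to match — fixed once in the defaults. Each column draws from its
own RNG stream derived from the master seed, so reconfiguring one
distribution leaves the other columns bit-identical.

Planted dominants are created by post-hoc overwrite: the first k drawn
rows receive a strict per-table maximum on every increase-preferred
criterion, floodplain present, low-elevation clear. Overwriting is exact
where rejection sampling would be approximate. The default is a single
dominant: multiple dominants are written as identical rows, and under
average-rank ties identical rows cannot all hold rank 1, so the clean
recovery property (rank 1 in every one of the 28 runs, membership in
`both`) is stated and tested for k = 1. Tabular-mode adjacency is a
nearest-centroid graph (each row linked to its ≤ 4 nearest centroids,
symmetrized) standing in for polygon contiguity; region labels follow the
centroid's block of the unit square.

`gen_landscape()` builds a south-tilted plane (10 m relief) with ±0.3 m
uniform noise, one carved channel walked from the north to the south edge
with strictly decreasing elevations (guaranteeing the D8 system an
outlet), nearest-seed tessellations for land use and soils (contiguous
patches), water on the channel, a two-cell channel buffer as the
floodplain, and a binary patch mosaic for climate flow.

What the synthetic system does *not* emulate: spatial autocorrelation
beyond patch contiguity, realistic absolute load magnitudes, correlations
among criteria (columns are independent by construction), or the
morphology of real stream networks. Passing recovery tests therefore
demonstrates the pipeline's correctness and determinism, not predictive
skill on real landscapes.

## Problem sizes and numerical tolerances

The test suite runs synthetic tables of 40–500 alternatives, grids from
2×2 to 30×40, brute-force oracle comparisons on n ≤ 8 alternatives and
10×10 grids (score agreement to 1e−12), 20 random 15×15 DEMs for the
hydrology properties, and 1000 random coded tables for dominance
transitivity — sizes chosen so the whole suite completes in well under a
minute while still exercising every code path. Eigen-residuals are held
to 1e−8; all other comparisons are exact or at `testthat` default
tolerance.

## Known limitations

- D8 is single-flow-direction; divergent flow (D∞) is out of scope.
- Watershed delineation reproduces the stated contract (cells whose flow
  path enters the patch), not any particular GIS toolkit's internals.
- Raster-mode patch adjacency treats components within a one-cell gap as
  adjacent, since maximal components can never literally touch.
- Weights come only from the two-objective apportionment scheme; no
  elicitation machinery is provided.
- Region discovery is input, not inference.
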