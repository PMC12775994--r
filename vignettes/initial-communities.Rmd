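---
title: "From plot-imputation rasters to LANDIS-II initial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From plot-imputation rasters to LANDIS-II initial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricb)
```

LANDIS-II initializes a simulation from two files: an integer raster whose
cell values ("map codes", 0 = inactive) index into a lookup table of
species–age–biomass cohorts. `ricb` assembles both from a plot-imputation
raster (each forested pixel holds the id of the inventory plot that best
represents it) and a tree-level database for those plots. This vignette
explains the model assumptions, the tunable parameters, the numerical
choices, and what the synthetic-landscape tests do and do not demonstrate.

## Allometric biomass

Total aboveground dry biomass per tree is the Jenkins group-level
allometry, `bm = exp(B1 + B2 ln(2.54 DIA))` with `DIA` in inches and `bm`
in kg. The coefficients travel with the species reference table
(`SPECIES_SYMBOL → JENKINS_TOTAL_B1/B2`); the package treats them as user
data, so any coefficient revision is a table edit, not a code change.
`jenkins_biomass()` is undefined at `DIA = 0` and raises a domain error
there; the tile builder instead drops zero-diameter alive trees (saplings
below breast height) with a logged count, and — by convention — reports
both age and biomass as 0 for trees recorded with zero height.

## Age from site-index curves

Inventories record height, not age. Age is obtained by inverting the
Carmean height curve
\(H = b_1 S^{b_2}\,(1 - e^{b_3 A})^{b_4 S^{b_5}}\),
giving
\(A = \tfrac{1}{b_3}\ln\!\big(1 - (H/(b_1 S^{b_2}))^{1/(b_4 S^{b_5})}\big)\).
The curve family is constrained to its decay form (`b1 > 0`, `b3 < 0`), for
which the forward curve is strictly increasing in age toward the asymptote
\(b_1 S^{b_2}\) and the inverse is exact on \(0 \le H <\) asymptote. The
package implements *both* directions; the forward curve is what the
synthetic generator uses to manufacture heights, which is precisely what
makes the inversion testable against known truth.

Coefficients are keyed by eastern species group code (`E_SPGRPCD`): each
group uses the site curve of its representative species,
`representative_species()` — the species with the most individuals in the
group, ties broken by lexicographically smallest symbol so the result is
deterministic and order-independent.

Real inventories contain trees taller than their site curve's asymptote.
The inverse has no finite value there, and discarding the trees would
silently delete biomass, so such trees are clamped to `max_age_yr`
(default 300 years, roughly the age at which eastern site curves are flat)
and counted in the run log. Ages are kept fractional (e.g. 14.97 yr)
until cohort binning.

## From tiles to cohorts

Each plot's alive trees form a *landis tile*
(`MapCode,SPECIES_SYMBOL,COMMON_NAME,E_SPGRPCD,age,biomass`; MapCode blank
until spatial linkage). A tile is interpreted as fully describing **one
pixel** of the imputation grid; no per-tree expansion factors are applied.
Consequently the g/m² conversion is simply `kg × 1000 / cell_size²`, the
"pixel-area weighting" of the published workflow, and domain-wide species
totals weight each tile by the number of pixels imputed to its plot.

Species selection defaults to the strict `fraction > 0.01` rule; the 1%
cutoff is a presentation convention, not an estimate, so it is exposed as
`threshold` together with explicit `include`/`exclude` lists (the "niche
species" mechanism). Raising the threshold can only shrink the default
selection. Unselected species are dropped, not redistributed.

Cohort ages are `ceiling(age / timestep) × timestep` with a minimum of one
timestep: LANDIS-II cohorts must carry positive ages, and the ceiling rule
keeps a 14.97-year tree in the 15-year class at a 5-year timestep. Binning
only regroups biomass; for every timestep the pixel-weighted total grams
are conserved (asserted at 1e-6 relative in the tests, observed at machine
precision). The wood/leaf split is `leaf = leaf_fraction × total` with a
default of 0 — the published outputs print both columns without stating a
partition method, and inventing a foliage allometry here would be a
modeling claim the data do not support. Output biomass is written at full
precision; `round_int` reproduces integer-style tables (half away from
zero, cohorts rounding to zero dropped and logged).

## Spatial conventions

* The AOI is reprojected into the raster CRS, never the reverse: the
  imputation grid is the dataset and survives bit-exact. The built-in
  transform pair is geographic WGS84 (EPSG:4326) ↔ spherical Web Mercator
  (EPSG:3857), in exact closed form; other pairs are rejected rather than
  silently mis-projected.
* Cell membership uses the cell-center rule (deterministic and standard);
  boundary centers count as inside. Clipping is idempotent.
* Rasters are carried as ESRI ASCII grids with a `.prj` sidecar — a plain
  text, self-describing format with explicit nodata — and AOIs as GeoJSON
  or KML. Corrupt geometries (non-finite coordinates, fewer than three
  distinct vertices, zero area) fail with a geometry error before any
  spatial work starts.
* Mode aggregation collapses each `factor × factor` block to its most
  frequent non-nodata value; all-nodata blocks stay nodata, frequency ties
  break to the smallest code, and trailing partial blocks aggregate over
  the cells they actually contain. Factor 10 reproduces the 30 m → 300 m
  companion product.
* Sequential remapping sorts surviving plot ids ascending into `1..K`;
  nodata becomes 0 in the written map, the LANDIS-II inactive-cell value.

## The synthetic landscape generator

`generate_landscape()` emulates the statistical structure the pipeline
consumes — not forest dynamics. Defaults: a 60×60 grid of 30 m cells, 25
plots with random non-sequential 5-digit ids (so remapping is nontrivial),
10% nodata, 20–60 trees per plot, 15% standing dead, site indices 50–90 ft,
diameters 1–30 in, true ages 5–120 yr, and an 8-species southeastern
pine–hardwood pool with published Jenkins group coefficients. Heights are
produced by the *forward* Carmean curve from the drawn true ages, so the
age stage has an exact known answer; the AOI is a 15°-rotated interior
rectangle delivered in EPSG:4326 against an EPSG:3857 raster, so
reprojection and clipping are always exercised. Equal seeds give
byte-identical landscapes.

What passing tests therefore show: the arithmetic, contracts, and
conservation properties of the pipeline are correct. What they do not
show: anything about imputation quality on real landscapes — the generator
has no spatial autocorrelation of forest types, no diameter–height–age
covariance beyond the site curve, and no measurement error in heights.

## Problem sizes and checks

The test suite and the acceptance script run on 15×15 to 100×100 grids
with 5–50 plots (up to ~2,500 trees) — large enough that every species
appears in every abundance ranking and every code path (nodata, partial
blocks, empty map codes, clamping) is hit, while a full run takes seconds.
Key numerical checks: Jenkins evaluations against an independent direct
form at 1e-12 relative; 1,000 random forward/inverse Carmean round trips
at 1e-6 relative; mode aggregation against an exhaustive per-block
frequency oracle on 100 random grids; biomass conservation across
timesteps at 1e-6 relative; byte-identical reruns.

## Known limitations

* Only the EPSG:4326/EPSG:3857 CRS pair is built in; rasters in other
  projections must arrive with AOIs already in a supported CRS.
* Shapefile AOIs are not read (binary format); convert to GeoJSON or KML.
* No FIA trees-per-acre expansion factors: a tile is taken as the literal
  per-pixel community. If your tile biomass is per-acre expanded, the g/m²
  scale will be off by the expansion ratio.
* The wood/leaf split is a single global fraction, not a species-specific
  foliage allometry.
* Succession-extension-specific dialects (e.g. NECN climate/species files)
  are out of scope; the outputs are the generic initial-communities pair
  plus the parameterization list.
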