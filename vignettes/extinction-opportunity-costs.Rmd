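---
title: "Methods: extinction opportunity costs of food"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extinction opportunity costs of food}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifecost)
```

## The model

`lifecost` treats the biodiversity impact of food as an *opportunity cost*:
agricultural land kept in production forgoes the reduction in species
extinction risk that restoring it to natural habitat would deliver. The
quantity of account is ΔE — the change in the expected number of
extinctions summed over an assessed species set — expressed per km² of land
(the restore layer), per kg of commodity (production and consumption
impacts), per person-year (footprints) or per person-day (diets).

### Extinction risk and the restore layer

For each species the probability of extinction is related to its
proportional area of habitat (AOH) by a power law

$$p(A) = 1 - (A/A_0)^z,$$

with $A$ the current AOH, $A_0$ the AOH under a human-absent baseline and
$z > 0$ a dimensionless exponent. We default to $z = 0.25$, the classic
species–area exponent; it is a configuration field of the world, not a
fitted quantity. The form of the law is an emulation choice: the package
needs a concave, scale-free link between habitat loss and extinction risk
with the property that narrow-ranged species respond more strongly to a
fixed absolute change, and the power law is the canonical such link.

Restoring the agricultural area of one cell changes species $s$'s AOH by
$\delta A_s$, built per land-cover class (cropland, pasture) from the
species' suitability flags:

* natural suitable, agricultural class not tolerated: habitat is gained
  ($\delta A_s > 0$);
* both tolerated: no AOH change, zero contribution;
* only the agricultural class suitable: restoration removes habitat
  ($\delta A_s < 0$).

The cell's restore density is $\sum_s [p_s(A_s) - p_s(A_s + \delta A_s)]$
divided by the restored (agricultural) area, in ΔE km⁻². All species count
equally; there is no threat-status weighting. Cells with no agricultural
area score zero (there is nothing to restore). $A + \delta A$ is clamped to
$[0, A_0]$ so degenerate constructed inputs cannot push the ratio outside
the law's domain; inputs with $A > A_0$ are rejected as invariant
violations rather than clamped, since they indicate inconsistent data.

### From densities to per-kg impacts

Per producing cell, the impact of one kg is
`density × harvested_area / production` (production converted to kg). The
national value is the **production-mass-weighted median** over the
country's producing cells; global and group distributions are weighted
10th/50th/90th percentiles over national medians (groups pool
commodity × country values). Two conventions are deliberate:

* **Lower-value (type-1) weighted quantiles, no interpolation.** With
  integer weights this is exactly the plain quantile of the expanded
  sample — an oracle the tests exploit — and it is invariant under weight
  rescaling. An interpolating definition would manufacture values that no
  cell attains and would not commute with the expansion oracle.
* **Cell weights are production mass,** not harvested area, matching the
  mass-weighted global aggregation; `compute_impacts(cell_weighting =
  "area")` switches conventions, since the cell-level choice is genuinely
  underdetermined and area weighting emphasises extensive low-yield land.

Cells with missing (nodata) restore density are excluded from medians
rather than treated as zero; a zero would silently understate impacts. A
country with no production of a commodity has *no* per-kg value (`NA`,
"defined-absent") — again not zero — and callers must handle it.

### Animal products

An animal commodity's per-kg production impact is the sum of

* a **grazing component**: the country's grazing restore density — the
  livestock-weighted median of restore densities over pasture cells,
  weights being head counts (density × pasture area) — times the grazing
  requirement $G$ (km²·yr per kg product); and
* a **feed component**: $\sum_f \mathrm{req}_f \times w_f$, feed
  requirements (kg feed per kg product) times the feed crop's
  *consumption-basis* impact in the producing country.

Valuing feed at consumption basis is what lets feed grown on another
continent carry its true origin's impacts into the animal product. The
grazing aggregate uses a median for consistency with the cropland
aggregation (a weighted mean is available); the requirement tables $G$ and
`req` are exogenous inputs — global grazing "yields" are not observable at
commodity level, so the synthetic generator supplies them.

Defaults are anchored to familiar magnitudes: beef-like products ~2×10⁻⁴
km²·yr/kg of pasture (~20 m²·yr per 100 g), dairy/eggs ~2×10⁻⁶, monogastrics
none; feed conversion 2.5 kg grain-equivalent per kg pig/poultry meat, 2.0
for ruminant meat, 0.8 for dairy/eggs, each with a smaller legume share.

### Trade provenance

Bilateral flows are first expressed in primary equivalents (mass divided by
the extraction rate, accumulated onto the primary commodity; one-level
commodity tree). The re-export correction then finds each country's
origin mix $F$ as the fixed point

$$F_{i\cdot} = \frac{P_i}{s_i} e_i + \sum_j \frac{T_{j\to i}}{s_i} F_{j\cdot},
\qquad s_i = P_i + \textstyle\sum_j T_{j \to i},$$

solved exactly as a dense linear system: exports carry the exporter's
supply mix, so the same portfolio applies to domestic use. The linear
solve is order-independent and exact; a fixed-point iteration is kept
purely as an independent oracle (agreement within 10⁻¹⁰ on random networks
is a test invariant). Degenerate cases are explicit: zero-supply countries
are dropped (with a warning if they record use) and cannot be origins;
exports exceeding supply are scaled down proportionally with a warning
(real mirror-statistics artefacts; synthetic tables never trigger it); a
closed re-export cycle with no production anywhere has no valid solution
and is an error in both solvers, not a silent zero.

### Footprints and the marginality guard

A country's per-capita footprint is $\sum_c q_c w_c$ over consumed
commodities ($q$ the FAO-style food supply in kg/person/yr — waste is
embedded in those accounts, so no separate waste correction is applied).
Sugar is excluded from consumption analyses by default because its supply
chains cannot be attributed to beet or cane; the exclusion is a flag, so
production-side sugar analyses are unaffected. The import/domestic split
traces impacts to **ultimate** origins: feed embedded in a domestically
produced animal product is credited to the countries that grew the feed.
This extends the direct-origin formula (to which it reduces exactly for
crops) and follows the motivating case of imported soy feeding domestic
livestock.

The restore layer is marginal: aggregating it is only reliable for
land-cover changes up to roughly 1,000 km², beyond which deviation from a
full recomputation exceeds ~10%. `implied_land_and_marginality()` converts
any basket into km² (crop land via provenance-weighted area/production,
animal products adding grazing and feed land) and warns past the
threshold. Per-capita baskets sit around 0.01 km²; national aggregates on
the standard worlds exceed the threshold and do warn, which is the point.

### Diet scenarios

A diet spec is a set of energy fractions over seven food groups plus a
total (default 3,911 kcal/person/day, the baseline the tables are
calibrated to). Held-constant commodities (stimulants/spices, which carry
negligible calories but non-negligible impacts) are copied from the
baseline and their calories netted off the allocatable budget *before*
fractions are applied — the bookkeeping choice that makes every built diet
match the baseline's total exactly, which the source accounts leave
unspecified. Within a group, commodities keep their baseline calorie
ratios; sugar receives calories but contributes zero impact. Provenance is
held at current sourcing, so a scenario is specific to the country it is
built for. Footprints are linear in intakes; ratios to baseline are
invariant under rescaling the restore layer (both are test invariants).

## The synthetic world

`generate_world()` produces every input the pipeline needs, deterministic
under a single seed (stage-specific substreams keep additions to the
generator from perturbing existing draws):

* a Voronoi partition of an abstract equal-area grid into countries
  (default cell 100 km²; no geographic CRS, removing projection and
  area-distortion logic from the testable core);
* land-cover fractions per cell (natural 0.25–0.75, remainder split
  pasture/cropland) summing to 1;
* a species set with circular ranges — endemics concentrated toward
  low-latitude rows when the tropics gradient is on, so restore densities
  reproduce the tropical skew of the real layer — and independent
  cropland/pasture tolerance flags (probability 0.25 each);
* the restore layer computed from those species;
* supply/trade accounts whose food-supply calorie shares follow an
  FAO-style baseline profile (grains/roots 35%, dairy/eggs 13%, poultry/pig
  10%, ruminant meat 4%, sugar and other 20%, …). Food targets plus feed
  demand determine production, so `production + imports − exports − feed −
  food = 0` holds *exactly*, with no stock residual; national food energy
  is sized so crop-area demand at base yields fills the country's
  cropland, keeping effective yields at realistic magnitudes (grains ~300
  t/km², vegetables ~1,500, legumes ~150, sugar crops ~5,000, stimulants
  ~80);
* cropland allocated to commodities within each country in proportion to
  area demand, gridded production rescaled so national sums equal the
  tables bit-for-bit at the 10⁻⁹ level;
* populations derived from total food energy, so baseline supply delivers
  exactly 3,911 kcal/person/day everywhere.

What the generator does **not** emulate: real biogeography or IUCN range
maps; land-use intensity; stock variation and mirror-statistic asymmetries
in trade; sub-national heterogeneity in diets. Passing tests therefore
demonstrate that the *accounting machinery* is correct and internally
consistent under the stated statistical structure — not that any particular
real-world number is reproduced. Headline ratios from the full global
datasets (e.g. ruminant-to-grain impact ratios in the hundreds) emerge here
with the right ordering and smaller magnitudes (~50–80×), as expected from
a world with hundreds rather than tens of thousands of species.

## Numerical choices

* Weighted quantiles compare cumulative weights against `q × total` with no
  epsilon; with integer weights this reproduces the expansion oracle
  bit-for-bit, including boundary `q`.
* The no-trade identity (consumption ≡ production, imported share exactly
  0) holds *bitwise*: the feed component is accumulated through the feed
  crops' origin decompositions so the total and its origin split are the
  same floating-point sum.
* Scaling laws (yields ×k ⇒ impacts ÷k; restore layer ×k ⇒ impacts and
  footprints ×k) are exact in exact arithmetic and tested bit-exactly with
  power-of-two factors, at 10⁻¹² relative tolerance for generic factors.
* Provenance: linear solve, singularity rejected via determinant and a
  row-sum check (a deficient solution means a production-less cycle);
  row-stochasticity enforced to 10⁻⁹ in tests, mass conservation to 10⁻⁶
  relative.
* Serialization: rasters as ESRI ASCII grids written with `%.17g`
  (float64-exact round trip); tables as long-format CSV with full-precision
  values; all pipeline writes are atomic (temp file + rename) and carry no
  timestamps, so identical configs give byte-identical output trees.

## Problem sizes

The default test worlds are 12×12 cells, 3 countries, 30 species; property
suites run hundreds of random cases (10,000 for the quantile oracle, 1,000
random trade networks up to 20 countries); the end-to-end determinism check
runs the full pipeline twice on a 100×100-cell world with 12 countries, 10
commodities and 200 species. These sizes keep the whole suite under a
minute while exercising every code path at the scales the invariants are
stated for.

## Known limitations

* Single-level commodity tree (each processed commodity maps to one
  primary); deep FAO trees are out of scope.
* No herd demography or milk/meat co-product allocation — one requirement
  table per animal product stands in.
* The generator's habitat model is binary (suitable or not) per land-cover
  class; intensity and habitat-quality gradients are not represented.
* Zero-footprint countries (possible in sparse synthetic worlds) have an
  undefined import/domestic split, reported as absent rather than
  invented.
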