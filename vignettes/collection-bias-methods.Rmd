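---
title: "Methods: quantifying collection bias in type-specimen records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying collection bias in type-specimen records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(typebias)
```

`typebias` measures how a flora's documented history — here, the type
specimens of a large plant family collected in one under-documented
country — was shaped by who collected, when, and how accessible each
place was. This vignette explains the models and procedures, the
defaults and why they were chosen, what the synthetic generator does
and does not emulate, and the numerical decisions a maintainer would
want written down.

## Record handling and inclusion rules

Records arrive as Darwin-Core-style CSV; only a header mapping is
configurable. Missing cells stay missing — no field is ever defaulted,
because imputation at ingest would silently bias every downstream
count. Coordinates outside valid ranges reject the record with a
warning rather than being clamped: a clamped coordinate is a plausible
but wrong location, which is worse than an absent one.

Temporal analyses apply two rules. Neotypes are excluded: they are
designated long after the original material is lost, so their
collection dates say nothing about discovery and would produce
negative collection-to-publication lags. And when a taxon has several
types (syntype or paratype series), only the earliest dated specimen
is kept, avoiding pseudoreplication of the discovery event. The
tie-break within a year — holotype before lectotype before isotype
before syntype, isosyntype, paratype, isoparatype, then smallest
specimen id — is our choice; any fixed order would do, but a fixed
order there must be, or repeated runs reorder ties.

Some historical records carry no parseable year but can be assigned a
decade from expedition history. A side table of
(collector-or-specimen, decade) overrides supplies these; an
overridden record is placed at the decade for binning and at the
decade midpoint (start + 5) when a scalar year is needed (lags,
career spans). Overrides never mutate the source table.

Free-text dates are reduced to the earliest four-digit year they
contain, so a range such as "1890–1902" dates the record to 1890 —
the conservative choice for discovery chronology.

## The collector-importance index

For each collector we count type specimens (`nesp`), distinct
provinces (`nlocality`) and career span in years (`duration`), min–max
normalise each across collectors, and combine them with weights
0.5 / 0.3 / 0.2. The weights encode a judgement — specimens matter
most, then spatial reach, then persistence — so the package also
reports how the top-*k* set changes when each weight is perturbed by
±0.05 and ±0.10 (renormalised); a ranking that survives that grid is
not an artefact of the weights.

Two conventions deserve note. Joint collections credit every
co-collector with the whole specimen (a fractional mode exists but is
off by default): the phrase "collected by A & B" describes two people
collecting one gathering, not half a gathering each. And when a metric
is constant across collectors, its normalised value is 0 for everyone
rather than 0.5, so a non-informative metric contributes nothing and
the index keeps its reading as "share of the best observed".

The duration–productivity association is tested with a Spearman
correlation: rho is the Pearson correlation of average ranks; the
two-sided p-value uses the t approximation for n ≥ 10 and exact
permutation enumeration below that, where the approximation is poor
and the enumeration cheap.

## Temporal series

Collections and publications are aggregated by decade, labelled by
starting year (the 1940s are 1940–1949). Records before 1820 are
excluded by default (configurable): the earliest decades are so sparse
that a single specimen would dominate a curve. Publication counts one
event per taxon at its protologue year; when a type series disagrees
about that year the minimum is used with a warning, since the earliest
plausible protologue bounds the description date from below. The lag
statistic is publication year minus earliest collection year, averaged
overall and by decade of collection — the decade in which the taxon
entered scientific knowledge. Negative lags are flagged and excluded
with a warning: they signal a data error (typically neotype leakage or
a wrong protologue year), and in the synthetic world they arise when
the earliest specimen's year has been deleted by the missingness
process. The overall mean is taken over the same taxa as the per-decade
means, so the count-weighted decade means reproduce it exactly — a
property the tests assert.

## Density surfaces and region tables

Collection effort is smoothed with a product-Gaussian kernel over
longitude/latitude, on a 100×100 grid padded three bandwidths beyond
the data. The default bandwidth per axis is the normal-reference rule
h = 1.06 · min(sd, IQR/1.34) · n^(−1/5). Coordinates are treated as
planar degrees: these surfaces are visualisation semantics (hotspot
maps), and at the latitudes of the reference use case the anisotropy
is modest; no conclusion in the pipeline depends on absolute density
values.

Region tables assign each georeferenced point to named polygons.
Provinces and ecoregions are partitions: a point on a shared boundary
counts once, for the lexicographically first containing unit — an
arbitrary but deterministic rule. Centres of endemism and important
plant areas overlap, so there a point may count several times.
Containment uses the even-odd rule with boundary points counted
inside. Percentages are rounded half away from zero to integer
percent, matching the printed-table convention, so blocks can sum to
99–101.

Because no GeoTIFF/shapefile reader is available in the target
environment, rasters travel as ESRI ASCII grids and vector layers as
GeoJSON — both plain text, both lossless for these purposes.

## The predictor table

Rasters live on a WGS84 grid; other layers align to the elevation
template by nearest-neighbour resampling. Slope is derived in degrees
by Horn's 3×3 stencil with degree-to-metre conversion per row
(111,320 m per degree latitude, scaled by cos(latitude) for
longitude) and replicated borders. Land cover is reclassified to six
ecological categories (agriculture/croplands, forest/tree cover,
grassland/shrubland, wetland/riparian, urban/bare, water). Point
extraction is half-open — a point on a shared edge belongs to the cell
east/south of it — so no point can be counted twice.

Distances to the nearest road and harbour are great-circle
(haversine, R = 6,371,000 m) to the nearest feature vertex, with
polylines densified to a maximum vertex spacing beforehand (100 m by
default, giving ≤ ~50 m error versus exact point-to-segment
geodesics — immaterial at landscape scale).

Pseudo-absences are drawn uniformly over the presence bounding box,
one per presence by default ("balanced"), with a fixed seed. No
land/ocean mask is applied by default — the bounding box is sampled as
is — but a mask option exists and its use matters: masking shifts the
availability distribution and hence the coefficients.

## The collection-probability model

The binary response (presence = 1, pseudo-absence = 0) is modelled
with a binomial GLM, logit link, fitted by iteratively reweighted
least squares from β = 0, converging when the relative deviance change
drops below 1e-8 (at most 100 iterations, with step-halving so the
deviance never increases). Standard errors come from the inverse
Fisher information at the optimum; p-values are two-sided Wald normal,
uncorrected — one model, five predictors, no multiplicity to correct.
Continuous predictors stay on their raw scale so coefficients read as
per-metre and per-degree effects. A fit with any |β| > 15 is flagged
as probable complete separation. Candidate models — null, each single
predictor, environment-only, accessibility-only, full — are ranked by
AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), with McFadden pseudo-R²
(1 − ℓ/ℓ₀) and ROC AUC (Mann–Whitney rank form with midrank ties)
reported alongside.

Land cover is a nominal variable and enters as treatment-coded
dummies (reference: agriculture/croplands) by default. An `integer`
encoding — a single coefficient on the class code 1–6 — is also
provided because published per-predictor coefficient tables sometimes
print one land-cover coefficient, which only an integer coding
produces; it is labelled non-recommended, as it imposes an ordering
the categories do not have.

## The synthetic world and what a green test establishes

The generator states a world: elevation as seeded Gaussian massifs
(≤ ~2,400 m) plus smoothed noise over a 6°×10° extent at 0.05°
cells; land cover as quantile slices of a second smoothed field (six
near-equifrequent classes); eight roads crossing the extent; five
harbours on the eastern edge (the coast analogy). Collection
histories allocate 273 specimens among 64 collectors (the scale of
the reference dataset) with lognormal productivity (σ = 1.5, so a
handful of collectors dominate, as observed), activity windows within
1820–2010, provinces drawn from a 10-unit partition with a
south/central bias, description lags gamma-distributed with shape 2
and mean 18 years (the reference mean; shape 2 gives the right-skewed,
non-negative lags seen in real chronologies), 10% missing years, 35%
synonym taxa and 2% neotypes to exercise the filters.

Presences are drawn by rejection: uniform candidates accepted with
probability inverse-logit(η). The default coefficients follow the
empirically expected sign pattern — positive elevation, slope and
land-cover effects, negative distance effects — with magnitudes chosen
once so that acceptance probabilities are small everywhere
(mean ≈ 0.008, maximum ≈ 0.12). That rare-presence regime is not
cosmetic: a logistic fit of presences against uniform pseudo-absences
estimates the slope coefficients of the generative model only in the
rare limit, and identifies the intercept only up to −log(mean
acceptance probability) — the standard use-availability result. The
generator therefore records the realised mean acceptance probability
as part of the ground truth, and recovery checks compare slopes to the
generative slopes and the intercept to its offset-corrected value.
Within the synthetic pipeline, road polylines are densified at 10 km
(not 100 m) for speed; generation and fitting share the same vertex
set, so this changes the definition of the distance predictor, not the
correctness of recovery.

A green recovery test therefore establishes that the pipeline
correctly estimates a known accessibility/environment model from
points it generated itself. It does not establish that the real
landscape layers are adequate, that georeferencing error is ignorable,
or that current land cover describes historical collecting conditions
— the known temporal-mismatch limitation of modelling historical
records against present-day layers.

## Numerical choices, edge cases, known limitations

- Min–max normalisation with max = min returns all zeros (see above);
  non-finite inputs are an error, never silently dropped.
- KDE with coincident points and no explicit bandwidth is an error
  (the reference rule degenerates); with an explicit bandwidth it
  works.
- AICc is undefined at n ≤ k + 1 and errors rather than returning
  ±Inf.
- Collinear design columns raise an error naming the columns;
  constant columns are dropped with a warning instead, since a
  constant predictor is usually an artefact of subsetting.
- The exact-permutation Spearman p enumerates all n! rank
  permutations; it is restricted to n < 10 where that is cheap.
- Percentages are rounded half away from zero, not banker's
  rounding, to match printed tables.
- Name canonicalisation is deliberately conservative (case-folding,
  whitespace, initials punctuation, an explicit alias table); no
  fuzzy matching, because silently merging two collectors is a worse
  failure than listing one person twice.
- The published whole-dataset statistics (273 specimens, 258
  georeferenced, 64 collectors, an 18-year mean lag) can be
  recomputed by `dataset_reproduction_stats()` only when the external
  curated table is supplied; the package ships only the published
  summary counts as fixtures.
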