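---
title: "Assigning geomasked survey clusters to districts and estimating coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning geomasked survey clusters to districts and estimating coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geomaskr)
```

## The displacement model

DHS-style geomasking displaces a cluster centroid by a two-step draw: a
distance and a bearing, drawn independently. The bearing is uniform on
$[0, 2\pi)$; the distance is uniform on $[0, d_{\max}]$ with
$d_{\max} = 2$ km for urban clusters and $d_{\max} = 5$ km for rural ones.
A documented 1% rural tail with $d_{\max} = 10$ km exists in the protocol;
it is implemented behind `include_one_percent_rule` but off by default,
because a 1-in-100 event per cluster contributes almost nothing to
district likelihoods while tripling the reach of the simulation disc.

Two points about this law matter for everything downstream:

* **It is uniform in distance, not in area.** An area-uniform ("dart
  board") draw would have density proportional to $r$; the geomask's
  density in the plane is proportional to $1/r$, concentrating possible
  origins near the released point. The package draws
  $r = d_{\max} U$; an `area_uniform` flag ($r = d_{\max}\sqrt{U}$) is
  provided only for sensitivity analysis.
* **It is radially symmetric**, which is what justifies inverting it by
  re-displacement: the density of the true origin given the released
  point is the same function of distance as the density of the released
  point given the origin. Whether distance or bearing is drawn first is
  immaterial for independent draws.

Displacements are converted to coordinates with the forward geodesic on a
sphere of radius 6371.0088 km. At the $\le 10$ km scale of geomasking the
spherical formula is within 0.1% of a full ellipsoidal geodesic — far
below the resolution of any ADM2 polygon — and it is deterministic,
dependency-free and testable against closed forms. Origins within 1° of
the poles and longitudes near the antimeridian are unsupported.

## Randomness and reproducibility

Every cluster gets its own RNG stream seeded from a hash of
`(global seed, cluster_id)`. Results are therefore invariant to the order
in which clusters are processed, and any cluster's simulation can be
reproduced in isolation. All RNG use is wrapped so the caller's random
state is untouched.

## The three assignment methods

With $n_{\mathrm{sims}}$ simulated origins (default 1000) located in the
district polygons:

* **Method A** assigns each district the fraction of located simulations
  that fell in it. Simulated points that land outside every district
  (across the national border, in a lake digitized as a gap) are dropped
  and the remaining fractions renormalized: the true origin must lie in
  *some* district, so renormalization is the maximum-likelihood treatment
  under the displacement model. If every simulated point is unlocatable
  the cluster is reported as an assignment failure rather than silently
  dropped.
* **Method B** takes the district with the largest method-A fraction.
  Ties are broken toward the district containing the released coordinate
  when it is among the tied set (keeping B consistent with C), otherwise
  toward the smallest district id — deterministic and documented, since
  any tie-break here is a convention.
* **Method C** locates the released coordinate directly. A coordinate
  marginally outside every polygon snaps to the nearest boundary within
  0.5 km (configurable) — slack for GPS error and polygon digitization;
  beyond that it is an error, not a guess.

Point-in-polygon tests treat polygons as planar in lon/lat (standard at
ADM2 scale), are boundary-inclusive, and break shared-boundary ties toward
the smallest district id, so locating a point is a total, deterministic
function on the union of districts. District areas are computed by the
boundary line integral of $\sin\varphi\, d\lambda$ (an equal-area
transform), which makes areas of a partition exactly additive — shared
edges cancel term by term.

## Survey estimation

The coverage estimator for a district $\times$ indicator cell is the
weighted proportion $\hat p = \sum w_k y_k / \sum w_k$. For method A, a
record whose cluster has district fraction $p_d$ enters district $d$ with
weight $p_d \times$ its base weight — the product of the district
likelihood and the sampling weight — and keeps its original cluster and
stratum identity, so one cluster can contribute (fractionally) to several
districts while each record's total weight is conserved exactly.

Variance is by Taylor linearization with clusters as PSUs: scores
$z_k = w_k (y_k - \hat p)/\hat W$ are summed to cluster totals $z_{hc}$,
and $V = \sum_h \frac{n_h}{n_h - 1} \sum_c (z_{hc} - \bar z_h)^2$ over
strata $h$. Confidence intervals are logit-scale Wald intervals with a $t$
critical value on $df = \#\text{clusters} - \#\text{strata}$, which keeps
them inside $(0,1)$ and makes the interval vanish naturally — flagged "not
estimable" — when $\hat p \in \{0, 1\}$; a plain Wald interval is
available by flag. No finite-population correction is applied, following
survey-program convention.

Two conventions deserved explicit choices:

* **Singleton strata.** After disaggregating a national design to
  districts, many district-stratum cells hold a single cluster, where the
  within-stratum variance is undefined. The default "centered" rule scores
  a singleton against the mean cluster total of the whole district with
  factor 1 — the conservative convention — and a "certainty" rule (zero
  contribution) is available.
* **Rounding.** Estimates are carried at full precision; published-style
  change between two survey rounds is computed on integer percents,
  $\mathrm{round}(100\hat p_2) - \mathrm{round}(100\hat p_1)$, matching
  how such tables are printed.

## Agreement

Two vectors of district estimates are compared with Lin's concordance
correlation coefficient with biased (divide-by-$n$) moments, per the
original definition; an $(n-1)$ variant is behind a flag. The confidence
interval uses Fisher's $z$ transform with Lin's asymptotic variance and
normal quantiles, back-transformed by $\tanh$. At $|\rho_c| = 1$ the $z$
variance diverges, so exact agreement is flagged degenerate rather than
given a meaningless interval. The test suite checks this interval against
a jackknife and verifies $\ge 90\%$ empirical coverage of a known
population $\rho_c$ at $n = 26$ pairs over 500 replicates.

## What the synthetic generator emulates — and what it does not

`generate_country()` builds a grid of rectangular districts whose row
heights follow `cell_km`, so areas can span the order-of-magnitude spread
real ADM2 units show; rectangles keep boundary-crossing probabilities
analytically tractable for oracles (a Voronoi geography would be more
realistic but untestable in closed form). `generate_survey()` samples
cluster locations uniformly within districts, stratifies by district
$\times$ urban/rural (mirroring DHS practice), sets weights to the inverse
within-district sampling fraction, and draws outcomes
$y \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\mathrm{logit}(p_d) + u_c))$
with cluster effects $u_c \sim N(0, \sigma_c^2)$, default
$\sigma_c = 0.3$ — a moderate, DHS-plausible intra-cluster correlation.
Eligibility thinning (all households report the water-like indicator; 70%
have an under-5 child; 12% have an infant 0–5 months) reproduces the
precision hierarchy water > stunting > breastfeeding. Default district
prevalences are drawn once per seed from indicator-specific uniform
ranges — water (0.05, 0.6), stunting (0.3, 0.65), breastfeeding
(0.2, 0.7) — wide enough that agreement statistics are informative.

`apply_geomask()` displaces each true location once. It redraws
displacements that would leave the country entirely (actual DHS practice
keeps released points within the national border), and can emulate the
post-2009 protocol of masking within the origin district
(`constrain_within_district`).

The generator does **not** emulate population rasters, realistic
settlement clustering, spatially correlated prevalence surfaces, or
non-response patterns. Passing parameter recovery here shows the
assignment and estimation machinery is correct under the stated
displacement and sampling model; it does not certify performance on any
particular real survey, where boundary complexity and the spatial
distribution of clusters relative to boundaries drive how much geomasking
matters.

## Problem sizes and numerical choices

The validation study used throughout the tests and the acceptance script
is a 5×5-district country (edges ≥ 20 km), 20 clusters per district, 25
households per cluster, 1000 simulated origins per cluster — small enough
to run in seconds, large enough that the household-level indicator's
method-vs-truth CCC exceeds 0.90 comfortably across seeds. Monte-Carlo
tolerances in tests are set from the corresponding binomial or KS sampling
distributions at 3–4$\sigma$. Proportion normalization and weight
conservation are asserted to $10^{-9}$; they hold to machine precision.
On-boundary point tests use a $10^{-9}$-degree (≈0.1 mm) tolerance.

## Known limitations

* Boundary I/O is GeoJSON only, always WGS84; there is no reprojection
  engine, and files declaring a projected CRS are rejected rather than
  transformed.
* Geometry auto-repair is limited to ring closure and degenerate-vertex
  removal; self-intersecting or overlapping inputs are errors for the
  user to fix upstream.
* Method A does not weight candidate districts by population — the
  fractions reflect the displacement geometry only.
* Merged districts are represented as multipolygons of their parts
  (no dissolve of internal edges); equivalent for location and area,
  but the internal edge remains in the stored geometry.
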