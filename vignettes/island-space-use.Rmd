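---
title: "Methods: residency, activity space and site preference at island receiver arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residency, activity space and site preference at island receiver arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandrange)
```

## The problem

Passive acoustic telemetry monitors tagged animals with an array of fixed
receivers, each logging the identity and time of every decoded
transmission from a tag within range.  Around small oceanic islands such
arrays are used to ask how co-occurring predator species partition a
shared, spatially constrained habitat: who is present when, who uses
which sites, and how much their core areas overlap.  `islandrange`
implements that comparative analysis end to end — detection quality
control, residency and roaming indices, centre-of-activity (COA) tracks,
land-masked kernel utilisation distributions (UDs), cyclic seasonal
smoothers, and a permutational multivariate analysis of variance
(PERMANOVA) of proportional site use — together with a synthetic island
generator that provides ground truth for every stage.

## Coordinate frame

All distances, bandwidths and areas are metric, so positions are
projected once, on input, into a local equidistant tangent-plane frame
centred on the land-polygon centroid (`local_projection()`).  Northings
use the meridional radius of curvature and eastings the prime-vertical
radius, both at the midpoint latitude of each point.  We chose this over
a single-radius spherical azimuthal projection because the two curvature
radii differ by about 0.6% at mid-latitudes: a compromise spherical
radius leaves an azimuth-dependent distance error of roughly ±0.3%,
whereas the ellipsoidal tangent plane keeps pairwise distances within
about 0.1% of WGS84 geodesics for separations up to a few tens of
kilometres — comfortably inside the array scale this package targets.
Beyond ~100 km separations the flat-earth curvature error grows and a
true geodesic projection would be needed; island arrays never approach
that.

## Detection quality control

Three filters are applied in a fixed order by `qc_detections()`:

1. **Post-release trim** (`window_h = 48` hours): behaviour immediately
   after capture and tagging is not representative; the removal window
   is *closed* (a detection at exactly release + 48 h is removed).
2. **Shed-tag / dead-animal signature** (`shed_min_days = 7`,
   `shed_max_gap_h = 24`): a transmitter lying on the bottom near a
   receiver produces an unbroken terminal run of detections at a single
   site.  An animal is flagged when its terminal run is at one receiver,
   spans at least 7 days, and contains no silence longer than 24 h.  The
   whole animal is removed, not just the run — once the signature is
   present the earlier record cannot be trusted to end at a known time.
   The thresholds are configurable because the field description of the
   signature ("consecutive detections over multiple days") does not pin
   them down; 7 days with a 24-h gap tolerance separates cleanly the
   shed-tag simulations from legitimately resident animals, which break
   such runs by moving between neighbouring sites.
3. **Minimum detection period** (`min_period_days = 14`, strict):
   animals with a detection period of 14 days or less likely left the
   monitored area; retaining them would bias residency statistics
   upward.  Never-detected animals are reported separately — they are a
   real feature of island tagging programmes, not a data error.

**Detection-period conventions.**  The period can start either at the end
of the 48-h window (`convention = "post48"`, default) or at the release
date (`"tagging"`).  Both appear in the telemetry literature; the choice
changes the denominator of the residency index by up to two days plus
any delay before first detection.  The convention used is recorded in
the QC report.  Days are whole calendar days in a configurable local
timezone (default UTC+11), counted inclusive of both endpoint dates, so
a single-day record has period 1, not 0.

## Residency and roaming

For each animal, the **residency index** (ResI) is the number of days
with at least one detection anywhere in the array divided by the days in
the detection period, and the **roaming index** (RoI) is the number of
distinct receiver sites with detections divided by the number of sites
*available* to the animal.  Availability corrects for staggered receiver
deployments: a site counts as available if its deployment interval
overlaps the animal's detection period at all.  Any-overlap is the most
permissive reading; it is monotone (widening a deployment can only add
availability) and avoids arbitrary proportional-overlap thresholds.

Monthly indices use the same formulas within calendar months, with two
refinements: a month at the start or end of the period is kept only if
the period covers strictly more than 14 days of it (partial months give
unstable indices), and both the residency denominator and the roaming
availability are assessed against the in-period part of that month.
With no dropped months, the month-length-weighted mean of monthly ResI
reproduces the overall ResI exactly — a useful identity test.

**Size classes.**  Where a biological maturity cut-off is unavailable,
`size_split()` divides a species mechanistically at the largest gap
between consecutive sorted total lengths whose endpoints both lie in the
interquartile range (linear-interpolation quantiles).  The cut-off is
the gap midpoint by default; the gap edges are available via
`gap_rule` because the midpoint choice, while symmetric, is a
convention, and ties between equal gaps resolve toward the gap whose
midpoint is closest to the median.

## Centre-of-activity tracks and activity space

Raw detections pin an animal to receiver coordinates.  Following the
standard short-interval position-averaging approach, detections are
first jittered uniformly in distance (0–25 m) and angle around their
receiver, then averaged within 2-h bins anchored at local midnight to
give one COA per animal-bin.  The uniform-distance/uniform-angle jitter
is a design choice (the convention "±0–25 m away" fixes only the range);
it concentrates density slightly toward the receiver relative to
uniform-in-disc, which matches the physics of detection probability
declining with range.  Where several receivers are moored within a few
hundred metres (the west-coast cluster in the synthetic scenario),
keeping all of them would bias COAs toward that cluster, so redundant
sites are excluded by configuration before binning.  COAs that fall
inside the land polygon are reassigned to the nearest shoreline point by
orthogonal projection onto the polygon boundary.

Utilisation distributions are fixed-bandwidth bivariate Gaussian kernel
density estimates (`h = 300` m on both axes, no cross term) on a regular
grid (`cell = 50` m, padded 4h beyond the COA bounding box).  The
bandwidth is treated as a fixed, externally motivated scale — of the
order of the detection range — rather than data-driven, so that surfaces
are comparable across species and groups.  Cell size 50 m resolves the
kernel (h/cell = 6) while keeping grids small; halving it changes level
areas by well under one percent.  Land cells are zeroed and the surface
renormalised over water (the default); the alternative
`mask_mode = "clip"`, which ranks cells on the unmasked surface and
merely excludes land from area counts, is provided because published
analyses are often ambiguous about which was done.  The level-p UD is
the smallest set of cells whose mass reaches p, with ties broken by cell
index so results are deterministic; its area is the cell count times the
cell area.  For a single COA this construction reproduces the analytic
Gaussian highest-density region, area = pi * (-2 ln(1 - p)) * h^2, to
within one cell — the package's primary numerical check.

Overlap between two groups at a level is the area of intersection of
their level sets divided by the arithmetic mean of the two level areas:
1 for identical surfaces, 0 for disjoint ones, and never above 1 since
the intersection is contained in both sets.  Grids being compared must
share origin and extent; the pipeline builds all groups on one common
grid.

For KDE evaluation the package uses an exact separable computation for
up to a few thousand COAs and a binned separable convolution above that;
with cell = 50 m and h = 300 m the binning displacement is at most 35 m,
two orders of magnitude below the kernel scale, and the two paths agree
to well under 1% pointwise.

## Seasonal smoothing

Monthly indices are fitted with a generalized additive mixed model:
a cyclic cubic regression spline on month (k = 12, knots wrapped at
month 0.5/12.5 so December and January are adjacent) per species, plus
animal and year random intercepts, estimated by REML via `mgcv`.  The
random intercepts absorb repeated measures on the same animal and
year-to-year level shifts; random slopes are deliberately omitted (the
data are monthly means, and slope variation is not separable from the
smooth at k = 12 with typical sample sizes).  The indices live on
[0, 1] but are fitted on the identity scale with Gaussian errors by
default — the conventional choice for index responses in this
literature — with an empirical-logit option (`transform = "logit"`)
where boundary saturation matters.  An exactly constant response is
detected and short-circuited to a flat fit with p = 1 rather than
passed to the optimizer with zero residual variance.

Significance of each species' smooth is the model's approximate
Wald-type test against a flat function; under null simulations its size
is close to nominal (the acceptance suite checks 0.05 ± 0.02).  Because
penalized-smooth p-values are approximate, a permutation alternative is
provided: month labels are shuffled within animal, the model refitted
with smoothing parameters frozen at the observed fit, and the
residual-sum-of-squares reduction attributable to the smooth compared
with its permutation distribution.  Its floor is 1/(n_perm + 1).

## Site preference

Proportional site use is an individual-by-site matrix of hourly
detection presences: several detections of an animal at one site within
one local hour count once, damping the dependence of counts on
transmitter interval and receiver proximity.  Rows are
individual-months by default — month then enters the PERMANOVA as a
factor — with `unit = "individual"` available to collapse months.  Sites
not deployed for the whole study, and the redundant cluster sites, are
excluded by configuration.

The PERMANOVA partitions the Bray–Curtis dissimilarity matrix by
sequential (Type-I) sums of squares on the Gower-centred inner-product
matrix; pseudo-F statistics are referred to free permutations of the
unit labels, p = (1 + #{F_perm >= F_obs}) / (1 + n_perm) with 999
permutations by default.  Sequential SS and the term order
(species, month, release site, sex, size) are configuration, not
doctrine: with unbalanced designs the decomposition depends on order,
so the order is recorded in the output.  Repeated individual-month rows
per animal violate strict exchangeability; free permutation matches the
common practice this package mirrors, and a `strata` argument restricts
permutations to within groups (e.g. within animal) for users who want
the conservative variant.  The pipeline drops terms that are incomplete
or aliased with earlier terms (for example, sex constant within species
in a small simulation) rather than aborting, and logs the decision.

On one-dimensional Euclidean data the pseudo-F reduces exactly to the
classical one-way ANOVA F; on small fixtures the Monte-Carlo p agrees
with exhaustive enumeration — both are asserted in the acceptance
suite, alongside an agreement check against an independent
implementation (`vegan::adonis2`), which the package uses only as a
test oracle, never as the engine.

## The synthetic island generator

`island_scenario()` defines the study conditions: an elliptical island
of about 8 x 5 km (~25 km coastline) with 21 receiver sites — a tight
three-receiver west-coast cluster at a hotspot, two pier pairs, a
coastal ring, a deep offshore group ~7 km south, and four sites
deployed only two years into the three-year window.  Four archetypes
span the behavioural space of a sympatric shark community:

* **migrant** (tiger-like): present in summer (monthly presence 0.85
  December–February, 0.02 June–October), highly mobile
  (`daily_transition = 0.5`), three-fold preference for the hotspot
  site;
* **pier residents A and B** (dusky-/Galapagos-like): year-round
  presence (0.55 and 0.5), strong attachment to their release pier and
  its neighbours with occasional island-wide excursions (ring sites at
  low weight — real resident sharks are detected at distant sites now
  and then, which keeps roaming indices away from degenerate lows);
* **offshore seasonal** (sandbar-like): attached to the offshore group
  only, reduced winter presence, slower transmitter interval
  (90–150 s vs 80–140 s).

Presence is drawn per *day* from the month's probability (constant
within a day), anchors persist across days with the transition
probability, and 2-h step positions scatter isotropically around the
anchor.  A per-step presence draw would decouple daily detection
probability from the programmed presence probability (a day would be
"present" with probability 1 - (1 - p)^12), breaking the design
requirement that an archetype programmed with daily presence p comes
back from the pipeline with mean residency near p; the per-day draw is
therefore part of the generator's contract.

Detections follow a logistic range model p(d) = 1 / (1 + exp((d -
d50)/s)) with d50 = 250 m (50% efficiency) and s = 50 m — the slope is
a design choice, as range testing typically reports only the 50% point;
50 m gives the gradual shoulder seen in published range curves.
Transmissions have i.i.d. uniform gaps on the transmitter interval and
are decoded independently by every active receiver.  Artefact injection
adds the two pathologies every real programme sees: never-detected
animals (tag metadata without detections; rates per archetype follow
the tagging outcomes the scenario emulates, up to half for the offshore
species) and shed tags (the record replaced from a random date by
continuous single-receiver pings, which the QC filter must catch).

What the generator does *not* emulate: tag collisions and close-proximity
detection interference, hydrodynamic/weather-driven range variation,
depth use, continuous movement within a 2-h step, and clock drift.
Passing the closed-loop tests therefore demonstrates that the analysis
machinery recovers programmed structure through a realistic
detection-geometry channel, not that it is robust to every field
artefact.

## Problem sizes and numerical choices

The test suite runs reduced scenarios (two to sixteen animals, windows
of a few months to two years) chosen so the full suite completes in a
few minutes while every qualitative contrast (seasonality, hotspot
preference, artefact recovery) remains detectable; the acceptance
script runs the full default scenario (32 animals, three years, ~21
receivers, several million detections).  Calibration checks use 200
null datasets for the PERMANOVA (rejection rate tolerance ±0.03) and
500 for the smoother (±0.02), sizes at which the Monte-Carlo error of a
0.05 rate is about 0.015 and 0.010 respectively.

Degenerate inputs are handled explicitly rather than left to optimizers:
zero-variance responses short-circuit the smoother; an all-land density
surface, empty COA sets, zero-row compositions, single-level factors and
aliased terms raise informative errors (or, in the pipeline, are dropped
with a logged message).  All randomness flows from explicit seeds; two
runs of the pipeline with the same configuration produce byte-identical
stage outputs.

## Known limitations

* The Gaussian identity-scale smoother can produce fitted index values
  slightly outside [0, 1] near the boundary; use the logit transform
  when that matters.
* Free permutation in the PERMANOVA treats individual-month rows as
  exchangeable; p-values for factors that vary only between animals are
  anti-conservative in the presence of strong individual site fidelity.
  The `strata` option is the remedy.
* UD overlap compares level *sets*, not full densities; two surfaces
  with identical 95% sets but different internal structure overlap at 1.
* The land mask supports outer rings only (no lagoons), and the
  flat-earth projection is for island-scale arrays, not archipelagos
  spanning hundreds of kilometres.
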