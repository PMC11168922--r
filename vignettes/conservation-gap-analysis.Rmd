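---
title: "Methods: conservation gap analysis with consgap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation gap analysis with consgap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consgap)
```

## The problem

Threatened species — those assessed as Vulnerable (VU), Endangered (EN) or
Critically Endangered (CR) on a Red List-style assessment — need
conservation interventions matched to the threats they actually face. A
species declining because its forest is being cleared needs habitat
protection; a species drained by international trade needs trade
controls; an island endemic being eaten by introduced rats needs invasive
species control. `consgap` implements a reproducible pipeline that, for
each species, (i) identifies its *major* threats, (ii) decides whether
each appropriate intervention is documented as in place, and (iii)
aggregates the apparent gaps by taxon, country and Red List trajectory.

Because the real inputs (Red List exports, protected-area databases,
habitat and elevation rasters, trade-listing and eradication databases)
are large and access-controlled, the package also ships a synthetic-world
generator that emulates all of their schemas with planted ground truth,
so the full pipeline is exercised end to end in the test suite.

## Threat model

Red List threat codes (levels 1–2 of the threat classification scheme)
are reclassified into six broad categories: habitat loss (including
degradation), overexploitation for international trade, pollution,
invasive species, climate change, and other. The mapping ships as an
editable CSV (`cbd_threat_mapping.csv`); it is a reconstruction covering
all level-1/level-2 codes and is deliberately configurable rather than
canonical.

A threat record counts as **major** when all three hold:

* **scope**: it affects more than 50% of the global population (the
  `majority_gt50` and `whole` scope classes);
* **severity**: it causes slow-significant, rapid or very rapid declines
  (`fluctuating` and `negligible` do not qualify);
* **timing**: it occurred in the past or is ongoing — never a predicted
  future threat. Both past variants (`past`,
  `past_unlikely_to_return`) are accepted; unknown timing never
  qualifies.

Records with *unknown* scope or severity may be included
(`include_unknown = TRUE`, the default), because real assessments very
often leave these fields unknown; the toggle reproduces the sensitivity
analysis of excluding them, and inclusion is monotone (turning it off can
only shrink the major-threat sets).

Two substantive restrictions are applied after reclassification:

* a record contributes **habitat loss** only if its stresses include an
  ecosystem/community stress (conversion, degradation, indirect effects).
  Threats such as recreational activities can stress individuals directly
  while leaving habitat intact, and must not count as habitat loss;
* an overexploitation record counts as **overexploitation for
  international trade** only when flagged as intentional use of an
  internationally traded species; otherwise (e.g. subsistence hunting) it
  falls into *other*.

## Protection model

All spatial computation happens on a planar equal-area grid. Rasters are
`nx` by `ny` matrices with a cell edge in km; vector geometries (ranges,
protected areas, islands) are unions of axis-aligned rectangles, for
which areas, intersections and per-cell coverage fractions are computed
*exactly*. This keeps the raster pipeline free of geometric approximation
and makes brute-force oracle tests meaningful to floating tolerance.
Real-world CRS handling is an input requirement, not a pipeline stage:
inputs must arrive in a planar equal-area coordinate system in km.

**Area of habitat (AOH).** A species' range is refined to cells with
suitable land cover and elevation: per cell, the suitable fraction is the
summed fractional cover of the species' suitable habitat classes (capped
at 1), zeroed outside the species' elevation limits and outside the
rasterized range. Ranges are rasterized by cell-centre membership with
half-open cells `[x, x + w)`, so boundary cells are never double-counted.
Level-1 habitat preferences conservatively expand to all nested level-2
classes; a species with no recorded preference treats all classes as
suitable, so only range and elevation refine.

**Representation threshold.** The minimum percentage of habitat that must
be protected is 100% for areas up to 10,000 km², 15% at 250,000 km² and
above, and linear in `log10(area)` in between:

$$T(A) = 100 - 85\,\frac{\log_{10} A - 4}{\log_{10}(2.5\times10^5) - 4},
\qquad 10^4 \le A \le 2.5\times 10^5 .$$

Any logarithm base yields the identical curve; base 10 is used. The curve
is continuous and non-increasing, verified on a 1,000-point grid in the
tests.

**Species Protection Score (SPS).** With overlap percentage $O$ (the
area-weighted share of the AOH inside protected areas, using exact
fractional per-cell PA coverage) and threshold $T$,

$$\mathrm{SPS} = \min\!\left(100,\; 100\,\frac{O}{T}\right).$$

Scores above 100 have no semantics here, so the score is capped. A
species is **meaningfully protected** iff its SPS is 100, i.e. $O \ge T$.
Numerically the comparison is `O >= T - 1e-9`: a relative float
discrepancy between two exact-arithmetic paths must never flip the
binary.

**Two bases, either rule.** The score is computed on up to two bases —
the unrefined expert range and the AOH — each with the threshold taken at
its own area (the conservative reading of an ambiguity: nothing in the
procedure forces the expert-range score to use the AOH area). The species
is meaningfully protected if *either* score is 100.

**Zero-AOH fallback.** Input limitations can zero the AOH (in this
package most often a range smaller than one grid cell that misses every
cell centre). Such a species is still credited with protection if an
occurrence record from the last five years (relative to a configurable
reference year, default the dataset year), buffered by 300 m for
positional error, intersects a protected area.

## Intervention model

Six intervention categories are tracked: PA occurrence, international
trade control, invasive species control, reintroduction, international
legislation, and education. Ex situ conservation is excluded throughout —
the focus is extinction risk in the wild.

The decision is a **cascade**: Red List tabular flag, else text-derived
flag, else category-specific external sources:

* **trade control**: any CITES-appendix listing of the species or a
  larger taxonomic group resolved through a supplied taxonomy table
  (absent taxonomy rows inherit nothing);
* **legislation**: a strict superset of trade control; additionally
  Species+-style listings (CITES, CMS, EU annexes) and account text
  naming a recognised multilateral agreement (matched against an editable
  shipped list);
* **invasive control**: for island species only, a *successful*
  eradication (in-progress and failed events never count) of an invasive
  vertebrate specifically named as threatening the species, on an island
  overlapping the species' range by any positive area. Island species are
  those with strictly more than 95% of their historical range area
  (polygons of all presence codes) on islands; eradication data are only
  reliable for islands, so continental species can qualify only through
  the cascade.

The cascade is an OR, so adding an evidence source can never retract a
status — a monotonicity property the test suite checks.

**Matched interventions and modes.** For the three major threats with a
clearly matched intervention: habitat loss ↦ meaningful habitat
protection; international trade ↦ trade control; invasive species ↦
invasive control. In `relaxed` mode the habitat criterion is *widened* to
meaningful protection OR mere recorded occurrence in at least one PA, so
the relaxed "addressed" and "documented" sets always contain the strict
ones. **Any documented intervention** means: meaningful habitat
protection (mode-appropriate) OR legislation (which subsumes trade
control) OR invasive control OR reintroduction OR education.

## Status changes

Status-change records are filtered to genuine changes: records flagged
non-genuine (new information, taxonomy) are dropped; a genuine change
later superseded by a non-genuine change in the *opposing direction* for
the same taxon is dropped together with its superseder (an apparent
improvement that was really a data correction); for taxa with several
surviving genuine changes only the first is kept. Supersession is judged
on direction, not exact category pairs, and a non-genuine change in the
*same* direction does not invalidate an earlier genuine one (the stricter
reading; the procedure's motivating case is an opposing-direction
correction). The category scale is ordered LC < NT < VU < EN < CR < EW <
EX, placing the extinct categories above CR so changes into and out of
them classify cleanly.

Cross-tabulations count uplists/downlists by (a) presence of any
documented intervention and (b), for species whose only major threat
among the three assessed is a given one, by whether its matched
intervention is in place.

## Aggregation and inference

Country summaries assign non-endemic species to every country of
occurrence (interventions are not spatially explicit, so attribution to a
subset of range countries would be arbitrary); statistical analyses focus
on country endemics. Proportions are modelled with grouped binomial GLMs
(standard IRLS via `stats::glm`) with terms for taxonomic class, Red List
category and their interaction, country, GDP, endemic counts and
evolutionary distinctiveness; inference is by single-term-deletion
likelihood-ratio tests against the χ² reference (no small-sample
correction, matching standard practice), respecting marginality for
interactions. GDP enters log-transformed — standard for a heavy-tailed
monetary covariate and configurable. Evolutionary distinctiveness is
standardized to `[0, 1]` within each taxonomic class so classes with
different ED scales are comparable. Non-convergence and separation are
surfaced as diagnostics on the fit object, never silently.

## The synthetic world

`generate_world()` builds: Dirichlet fractional habitat classes per cell;
a smooth sinusoidal elevation surface (default amplitude 3,000 m);
random-rectangle protected areas filling a target coverage (default 15%);
eight disjoint islands; vertical country bands with lognormal GDP;
species with log-uniform range sizes spanning 10³–10⁶ km² (so the
threshold curve's floor, interpolation and ceiling branches are all hit);
Red List-style threat records with configurable scope/severity/timing
distributions; evidence flags, listings, eradication events and
occurrence points.

The default cell edge is 100 km (cell area 10,000 km², the small-range
anchor), which deliberately produces a sizeable set of sub-cell ranges
with zero AOH, exercising the occurrence-point fallback. Island species
carry a named invasive-vertebrate threat with probability 0.6 — invasive
vertebrates being the dominant documented threat on islands — which keeps
the eradication route exercised at desk scale.

**Planting.** Each species is drawn neglected with probability
`neglect_prob` (default 0.58). Neglected species get no evidence flags,
no qualifying listings or eradications, and their ranges are
rejection-placed until the brute-force PA overlap sits at least 0.5 SPS
percentage points below the representation threshold on every scored
basis — a margin fixed at design time so that the planted label is
unambiguous under floating-point arithmetic. Non-neglected species that
draw no qualifying intervention are granted one tabular flag. Guards
ensure an eradication planted for one species never retroactively credits
a neglected species on the same island. `pa_coverage >= 1` emits a single
world-spanning PA (the exact saturation case) and is incompatible with
planting neglected species, so such configs require `neglect_prob = 0`.

Ground-truth labels are computed by generator-local brute force — naive
per-cell loops, an interval-sweep union-area routine, and
`stats::approx` for the threshold curve — never by calling the pipeline.
Exact recovery of every planted label is therefore a genuine end-to-end
check, not a tautology.

**What the generator does not emulate.** Realistic biogeography
(ranges are rectangles; countries are bands), taxonomy beyond a
three-level chain with unique genera, spatially autocorrelated threat or
evidence processes, assessor reporting bias, and real coordinate
reference systems. Passing tests therefore demonstrate that the
*decision logic* is implemented exactly as specified; they cannot
demonstrate that real Red List exports are free of the reporting biases
the method inherits from its sources.

## Numerical choices

* Exact rectangle arithmetic throughout (atom decomposition in the
  pipeline; an independent sweep-line in the generator and tests).
* Half-open cells and half-open membership tests; ties on cell edges are
  measure-zero for continuous random inputs.
* `SPS == 100` evaluated as `overlap >= threshold - 1e-9`.
* Empty ranges give AOH 0 (not an error); a species with neither
  geometry nor points is reported with basis `no_range_data` by the
  table driver and is an explicit error in the single-species function.
* Zero-area historical ranges return island status `FALSE` with a
  warning; degenerate rectangles are rejected at construction.

## Problem sizes used by the test suite

Chosen as the package's own desk-scale study conditions: 100 random
20×20-cell worlds for the raster-oracle equivalence (tolerance 1e-9); a
2,000-species world (fixed seed) for exact end-to-end label recovery,
with the estimated neglect proportion required to fall inside the
binomial 99% CI of the planted 0.58; 1,000 null replicates for LRT
calibration (Kolmogorov–Smirnov uniformity, p > 0.01) and 100 replicates
for effect recovery within 3 standard errors (≥ 95%).

## Known limitations

* Geometries are unions of axis-aligned rectangles; real range polygons
  must be pre-rasterized or approximated before entry.
* The shipped threat-code mapping and agreement list are editable
  reconstructions, not canonical standards.
* The pipeline measures *documented* interventions; absence of
  documentation is not evidence of absence of action, and the package
  cannot distinguish the two.
* Country attribution of non-endemic species inherits the
  non-spatial nature of the intervention records.
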