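---
title: "Counting seals in thermal aerial imagery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting seals in thermal aerial imagery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealtherm)
```

## The problem

Breeding colonies of grey seals are censused from aerial imagery. On a
cold winter landscape a hauled-out homeotherm is a bright object in a
thermal orthomosaic, so a per-pixel temperature map (a "thermal spatial
index", in °C) collected by a small drone at roughly 8 cm ground sampling
distance carries enough signal to detect, classify and count animals
automatically. Two things make the problem more than simple thresholding:

* **demography** — young-of-the-year (YOY) pups must be separated from
  adults, and the two classes overlap in temperature;
* **aggregation** — animals lying in contact threshold into a single
  merged warm object, which naive connected-component counting would
  record as one seal.

`sealtherm` implements a deterministic, rule-based census pipeline for
this setting, together with an accuracy assessment against human
annotation points and a synthetic scene generator that makes the whole
method testable without survey data.

## The pipeline

For a raster $T(r,c)$ with pixel area $g^2$ (default $g = 0.08$ m):

1. **Masking (optional).** Polygons drawn around landscape whose ambient
   temperature overlaps seal bodies are removed; a pixel is excluded when
   its centre lies in a mask polygon. Pixel-centre semantics are
   deterministic and match common GIS raster masking; partial-coverage
   weighting is deliberately not used.
2. **Thresholding.** Pixels with $T \ge t_{\min}$ are selected (the cut
   is inclusive). $t_{\min}$ is the one site-specific input of the whole
   method: the lowest temperature that still excludes the warmest
   landscape, chosen after brief visual inspection (9 °C at the training
   colony of the original survey; 5.5 °C at its colder prediction
   colony).
3. **Clustering.** Selected pixels are grouped into maximal connected
   components, rook (4-neighbour) connectivity by default: GIS
   raster-to-polygon conversion treats diagonal-only contact as separate
   polygons. Queen (8-neighbour) connectivity is available as an option.
4. **Polygonisation.** Each cluster becomes a polygon (union of pixel
   squares, holes preserved, no simplification) with three attributes:
   planar area $A = n_{\text{px}} g^2$; mean member temperature
   $\bar T$; and solidity $R$, the ratio of $A$ to the area of the
   cluster's convex hull. $A$ uses the exact pixel count rather than a
   simplified outline's shoelace area — the two coincide for unsimplified
   rasterised polygons. Holes subtract from $A$ but never enlarge the
   hull.
5. **Classification.** Labels are assigned by fixed-precedence rules
   (first match wins) with boundaries in m², solidity and °C:

   | label | rule (complex model) |
   |---|---|
   | individual YOY | $(A \le 0.85 \wedge \bar T < T^*) \vee A < 0.65$ |
   | individual adult | $(0.65 < A \le 3.5 \wedge R > 0.8 \wedge \bar T > T^*) \vee (0.85 < A \le 3.5 \wedge R > 0.8)$ |
   | YOY aggregation | $(0.65 < A < 0.85 \wedge R < 0.75) \vee (0.85 < A < 3.5 \wedge R < 0.8)$ |
   | adult aggregation | $A > 3.5 \wedge R < 0.8$ |

   The *simplified* model drops the temperature clauses: YOY are
   $A \le 0.85$ and adults $0.85 < A \le 3.5 \wedge R > 0.8$. The
   temperature split is $T^* = 10\,°C + \delta$, where the offset
   $\delta$ defaults to the difference between the site's detection
   threshold and the training value of 9 °C (so a 5.5 °C site implies
   $\delta = -3.5$ °C); `offset_temperature()` adjusts it explicitly.
6. **Aggregation splitting.** Aggregation polygons are re-examined on the
   raw temperatures: a zero-sum 3×3 high-pass kernel (centre 6.8,
   edge −1.0, corner −0.7 — the standard GIS HIGH filter; configurable)
   is convolved over the footprint's bounding window, cells with strictly
   positive response inside the footprint are re-clustered, and each
   component becomes one individual inheriting the parent's demographic
   class. Zero components — a featureless warm blob — fall back to a
   single individual, since a warm object above threshold is at least one
   animal. Split outputs are re-measured but not re-classified.
7. **Counting.** Totals are the sums of individual YOY and individual
   adult polygons.

Everything is a pure function of the raster and the parameter set, so
re-running the pipeline on identical inputs reproduces identical outputs.

### Why a zero-sum high-pass filter separates huddles

Inside a merged footprint each animal is a local temperature dome and the
contact lines between bodies are cool seams. A kernel whose coefficients
sum to zero annihilates locally constant temperature, responds positively
on domes (the centre weight dominates cooler neighbours) and negatively in
seams (the neighbours are warmer than the centre). Thresholding the
response at its natural flat-background level of 0 therefore selects one
positive region per animal. No minimum component size is applied — at
8 cm GSD a single warm pixel can be a real pup, so winnowing would
undercount.

### Decisions the rule table leaves open

* **Precedence.** The printed rules overlap (a cold, ragged 0.7 m²
  polygon satisfies both the complex individual-YOY and the
  YOY-aggregation rule) and leave gaps. `sealtherm` evaluates
  individual YOY → individual adult → YOY aggregation → adult
  aggregation, first match wins: individuals are claimed first and
  aggregations are the residual routed to splitting.
* **No match.** Polygons matching no rule (e.g. $A > 3.5$ with
  $R \ge 0.8$, or $R$ exactly 0.8) are labelled `unclassified`, excluded
  from counts, and carried in the result object so nothing is silently
  dropped.
* **Strictness.** Inequalities are applied exactly as written above,
  including the asymmetry between the individual bound ($\le 0.85$) and
  the aggregation bound ($< 0.85$), and the fact that a polygon with
  $\bar T$ exactly at $T^*$ fails both complex temperature clauses.

## Accuracy assessment

Human analysts place one class-labelled point per seal ("ITag points").
Assessment proceeds in two steps:

* **Snap.** A point already inside a prediction polygon is untouched; a
  point within 0.5 m (configurable) of its nearest polygon boundary is
  moved to the closest location on that polygon — compensating GPS error
  between the annotation and the raster. Nearest boundary wins; ties go
  to the lowest polygon id; the operation is idempotent.
* **Join.** Each individual prediction polygon is categorised by the
  points it contains: a matching-class point makes it a true positive;
  one point of each class makes it an adult/YOY *pair* (one object
  spanning two animals — this test precedes the true-positive test,
  otherwise the category could never fire for disjoint polygons); only
  other-class points make it *confused*, attributed to aggregation
  splitting when the polygon has a parent aggregation; no points at all
  means the model saw something humans did not annotate. Points inside no
  polygon are tallied as missed by the model. Per class, the categories
  partition the predictions, so their proportions sum to 1; a polygon
  holding several matching points still counts once.

## The synthetic scene generator

`generate_scene()` draws a seeded colony whose statistical structure is
exactly what the detector assumes, so end-to-end recovery of known truth
is a meaningful test of the implementation (not of the field method):

* **Background**: i.i.d. Gaussian ambient temperature (default
  2 ± 0.6 °C — a frozen shoreline well below the 9 °C threshold), plus
  dome-shaped warm landscape patches whose peaks stay below the
  threshold, as near-threshold confounders.
* **Seals**: each body is a capped-paraboloid "thermal dome" falling
  smoothly from a peak body temperature to ambient — a warm body blurred
  by sensor response. Domes enter the field through a pointwise maximum,
  so the threshold level set is exactly the union of per-seal footprint
  ellipses, whose area is solved from the configured planar area. YOY
  default to 0.25–0.60 m² at 12–14 °C, adults to 1.2–3.0 m² at 13–16 °C
  with elliptical aspect 1.6–2.8; the YOY upper bound sits below the
  0.65 m² rule boundary with margin for rasterisation jitter. Isolated
  footprints keep a ≥ 2-pixel gap, so nothing merges by accident.
* **Huddles**: aggregation members share size and body temperature and
  are circular, placed along an arc that curls in one direction. These
  choices are deliberate: equal circular domes meet along an exactly
  straight bisector (unequal elongated domes meet along conics whose
  second branch would carve phantom seams through a single body), and a
  curling chain is concave, which is what the solidity rule keys on.
  A cool seam of configurable depth (default 2 °C) is carved along each
  touching pair's contact line, masked out smoothly where a third member
  dominates (the three-way junction still receives full carve depth) and
  widened into a wedge where the footprint rim approaches the threshold,
  so the contact waist is notched cleanly instead of stranding one-pixel
  slivers. Members must keep a configurable core prominence (default
  1.5 °C) above their neighbours' domes at their own centre; placements
  violating it are redrawn. `huddle_scene_config()` packages these
  conditions.
* **Randomness**: one stream from the scene seed, consumed in a
  documented order (background → patches → isolated seals →
  aggregations); identical config and seed give bit-identical scenes, and
  the caller's RNG state is untouched.

What the generator does **not** emulate: photogrammetric mosaicking
artefacts, within-body temperature texture, wind chill gradients,
partially submerged or dead (cold) animals except as a degenerate
configuration, mixed-species scenes, and sensor calibration error.
Passing the synthetic recovery suite therefore demonstrates that the
implementation realises the method faithfully under the method's own
assumptions — not that the rule thresholds are correct for any particular
real colony.

## Problem sizes and numerical choices

The validation suite uses colonies of 40 YOY + 20 adults on a 50 × 50 m
scene (625 × 625 cells) across 20 seeds, and 100 huddle scenes of 2–5
members; these sizes exercise every code path (including polygons with
holes and single-pixel detections) while keeping a full run of tests plus
acceptance script in the low minutes on one core. Geometry is exact
rational-friendly arithmetic on pixel edges: traced outlines follow pixel
boundaries, shoelace areas reproduce $n_{\text{px}} g^2$ to machine
precision, and convex hulls are computed on exterior-ring vertices with
`grDevices::chull`. Convolution replicates the grid border and fills
nodata cells with their nearest valid value (deterministic tie order)
before filtering. World coordinates are metres in a projected CRS; row 1
is the northernmost row; pixel $(r,c)$ has centre
$(x_{\min} + (c-\tfrac12)g,\; y_{\max} - (r-\tfrac12)g)$. Geographic
(degree) coordinate systems are rejected rather than reprojected, because
every area rule is in m².

Raster I/O reads single-band float GeoTIFFs (georeference from an ESRI
world file, CRS from a `.prj` sidecar) and reads/writes ESRI ASCII grids;
vector products are GeoJSON (RFC 7946 ring winding) and CSV. These
plain-text formats keep every artefact inspectable and diff-able.

## Known limitations

* The high-pass kernel is the standard GIS HIGH filter; the original
  model's exact kernel is not published, so it is configurable
  (`high_pass_kernel()`), as is the post-filter selection threshold.
* Compact two- and three-member huddles are often convex enough to pass
  the solidity rule as large individuals — the same confusion the
  field method reports for mother/pup pairs. Splitting recovers their
  membership only when the classifier (or the caller) routes them to
  `split_aggregation()`.
* Split outputs are not re-classified by size, so an adult female inside
  a YOY aggregation inherits the YOY label; the accuracy table's
  pair/aggregation categories make this visible.
* Counts are per-polygon, so two animals annotated inside one individual
  polygon still count once — conservative by construction.
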