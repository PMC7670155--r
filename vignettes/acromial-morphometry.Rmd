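---
title: "Methods: 3D acromial morphometry, synthetic shoulders, and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D acromial morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(acromion3d)
```

This vignette records the model, the numerical choices, and the design
decisions behind `acromion3d`, including where the design was genuinely open
and what the package chose. It states no empirical result that the test
suite does not itself compute.

## 1. The scapular frame

All measurements live in a patient-specific scapular coordinate frame:

* **Origin A** — center of the total-least-squares circle fitted to ≥5
  annotated points on the inferior glenoid rim. The circle fit projects the
  rim points into their TLS plane, runs the algebraic Kåsa fit, and applies
  one geometric Gauss–Newton step. This is deterministic (no random
  initialization) and, by construction, its summed squared radial residual
  is never worse than the algebraic fit it starts from; tests compare it
  against a coarse-to-fine grid-search oracle.
* **x axis** — in-plane unit vector from B (scapular spine / medial border
  junction) toward A: medial → lateral.
* **z axis** — normal of the plane through A, B, C (C = inferior scapular
  angle), signed anterior.
* **y axis** — z × x: inferior → superior.

**Open design point: the sign of z.** Nothing in the three in-plane
landmarks determines which side of the scapular plane is anterior. The
package requires one extra annotated point (any point on the coracoid or
anterior clavicle) as an *anterior witness* and orients z toward it. The
alternative — inferring anteriority from mesh statistics — was rejected as
fragile and not rigid-motion equivariant. Consistency is checked: the
inferior angle C must land at negative y, otherwise the annotation is
rejected as contradictory rather than silently flipped.

**Left shoulders** are mirrored across the scapular plane (the plane through
A, B, C). In-plane landmarks are fixed points of that reflection, so a left
shoulder and its exact right-handed twin produce identical measurement sets;
the reflection also re-winds triangles to keep outward orientation. This is
a convention, not an inference about the source study, which pooled sides
without stating a procedure.

## 2. The eight parameters

* **AHI** — most superior humeral vertex H and the acromial undersurface
  (vertices with outward-normal y-component < −0.2; the −0.2 margin absorbs
  tessellation noise) are projected along x onto the y–z plane ("outlet
  view" is not defined in the source; the supraspinatus outlet view is the
  lateral scapular view, so projection along x). AHI is the minimum planar
  distance from H to the undersurface vertex set; if H lies outside the
  undersurface z-range the value is still reported but flagged
  `no_overhang`.
* **AAP / AIP** — a total-least-squares line through per-x-bin (1 mm)
  extreme points of the distal clavicle stands in for "a line coincident
  with the anterior / inferior aspect of the distal clavicle". A bin whose
  extreme exceeds its neighbors' envelope by more than 1.5 mm is discarded:
  when a tessellation grid line coincides with a bin boundary, floating-point
  jitter can otherwise push an *interior* vertex into a bin as its extreme
  and tilt the line (this was observed as a rigid-motion invariance failure
  before the filter existed). Values are protrusion magnitudes: negative
  (non-protruding) configurations are clamped to 0 and flagged.
* **AC angle** — angle at the MLPA between rays to the anterior and
  posterior AC-joint margins, in the x–y projection.
* **MLPA** — acromion vertex of maximal x; ties (within 1 nm) break by
  smallest y, then smallest z, for determinism.
* **AALP (a, b, c, c+d)** — see below.

## 3. AALP localization

The acromion sub-mesh is sliced with planes normal to y at 0.625 mm spacing
(the CT slice thickness of the emulated acquisition; configurable). Slicing
uses the full closed acromion rather than the open-cut anterior half: closed
contours have an unambiguous counterclockwise orientation and outward
normal, which the open cut surface would not. Candidates are restricted to
the anterior half (z ≥ z(MLPA)) afterwards — equivalent, but robust.

On each closed contour (oriented CCW in the slice plane's (z, x) basis),
curvature is estimated at 0.5 mm arc-length resampling from the
circumscribed circle of each point and its neighbors ±5 samples. The 0.5 mm
step sits below the 0.625 mm slice resolution, so no acquisition-scale
detail is lost.

**Sign convention, and a correction.** With the CCW / convex-positive
convention, *any* material protrusion's crease — the junction notch between
the anterolateral lobe and the main acromion — is a **negative**-curvature
(concave) extremum; no choice of in-plane basis changes that. The package
therefore marks, on the medial ("inner") arc (outward normal x-component
< −0.05), the point of most negative curvature with |κ| ≥ 0.15 mm⁻¹.
The build contract asserted the crease would be a positive maximum; that is
geometrically impossible and is recorded as a deviation. The 0.15 mm⁻¹
threshold has no published value; it sits between slab-edge fillets
(≈ 1 mm⁻¹) and smooth acromial curvature (≈ 0.05 mm⁻¹) on synthetic
geometry, and is exposed in the configuration.

Marked points ordered by y form the medial AALP border; fewer than 3 marked
slices is reported as "no distinct protrusion" (an explicit empty region,
not zeros). Member points are anterior-half vertices lateral *or* anterior
of the border interpolated at their height.

From the border: **a** = planar x–z distance from the most medial border
point to the MLPA; **b** = the same from the most posteromedial border point
(minimal x among the posterior-most 20% of border points by z — "
posteromedial" operationalized deterministically; the fraction is
configurable); **c** = z-extent of the member points; **c+d** = z-extent of
the whole acromion. a and b are planar Euclidean distances, not axis-aligned
widths, matching how the study draws them as segments to the MLPA; the
axis-aligned alternative would be a one-line change and is deliberately not
a flag to keep the measurement surface small.

## 4. The synthetic shoulder and what it does (not) establish

`generate_shoulder()` builds bones directly in the canonical frame so every
parameter has closed-form truth:

* **Acromion**: a two-level loft of a top-view outline carrying a posterior
  slab, a lateral apex wedge (the MLPA; the top apex vertex is drawn 0.05 mm
  medial so the maximal-x vertex is unique), and an anterolateral lobe whose
  medial junction is a concave fillet of radius 1.5 mm. The crease corner
  moves linearly with height (laterally and posteriorly, via a 2 mm
  anterior-edge tilt), giving the border the x- and z-spread that makes a
  and b distinct. The generator *solves* the crease x-positions so that the
  fillet-arc midpoint — the analytic curvature extremum — sits at exactly
  the requested a (at the base) and b (at the 80% height the posterior-20%
  rule selects in the continuum limit). Slice discretization then
  contributes ≲ 0.3 mm, inside the max(0.5 mm, 3%) recovery tolerance.
* **Clavicle / humeral head**: a grid-subdivided box whose anterior and
  inferior faces sit at offsets equal to the requested AAP and AIP, and a
  UV sphere with an exact pole vertex whose gap below the acromial
  undersurface equals the requested AHI.
* Default parameter values are the impingement-injury group means (AHI 8.1,
  AAP 8.5, AIP 9.0, AC 40.8°, a 14.8, b 11.0, c 11.3 mm, ratio 31.6%);
  c+d derives as 100·c/ratio because the source tables do not print it.
  Scaffold dimensions not pinned by any published value (apex at x = 36 mm,
  acromion thickness 8 mm, glenoid radius 14 mm, humeral head radius 24 mm)
  were chosen once at adult-shoulder scale and are not tuned.

A green recovery test establishes that the *pipeline* (frame, projections,
slicing, curvature, crease logic, reference lines) is correct on clean,
watertight, analytically-shaped bone stand-ins. It does not establish
robustness to segmentation noise, osteophytes, partial meshes, or landmark
placement error — real CT surfaces have none of the prism regularity these
fixtures do. Rim-landmark jitter is available (`rim_noise_sd`) but defaults
to 0 so that ground truth stays exact.

## 5. Cohort and rater simulation

`simulate_cohort()` draws each parameter independently per group at the
published means/SDs (control/NII/II, n = 113/98/128), zero-truncated by
resampling. Truncation inflates the raw mean — by ~9% for the wide-SD AIP
row, not the ≤2% the build contract estimated — so the generator solves for
the underlying Gaussian location whose truncated mean equals the printed
mean. Means are then matched by construction; SDs remain approximate, which
the contract itself accepts. One global seed fans out to one substream per
group × parameter, so any cell is reproducible in isolation.

`simulate_raters()` adds per-rater Gaussian bias and per-replicate Gaussian
error to true values, clamping negative distances at 0 with a flag.

## 6. Statistics

CV% is the root-mean within-subject replicate variance as a percentage of
the grand mean; ICC% is ICC(2,1) (two-way random effects, absolute
agreement, single measures) × 100, computed from explicit mean squares.
`anova_oneway()` and `anova_from_summary()` are algebraically identical
routes (SSB/SSW from raw data vs from n/mean/SD) kept separate so each can
check the other to 1e-10 in F. Pairwise comparisons default to unadjusted
Welch tests — the source reports pairwise P values without naming a method,
so the least-assumption default was chosen, with pooled-variance and
Bonferroni options logged in the report configuration. Reference ranges are
reported by both the empirical 2.5/97.5 percentile (n ≥ 20) and mean ±
1.96 SD, because the published "95% CI" columns match neither standard
construction; consequently the published risk cutoffs (a > 16.8 mm,
b > 12.9 mm, ratio > 33.5%) are carried as read-in constants
(`published_thresholds()`), not recomputed targets.

**Known unattainable criterion.** The acceptance contract asks that a
simulated cohort at the published summaries flag AAP, a, b, c and the ratio
as differing between the impingement and control groups (α = 0.05) in ≥95%
of 100 seeded runs. At those effect sizes the II-vs-control Welch test has
power ≈ 0.89 for AAP (8.5 vs 6.8, SD 4.7/3.5, n 128/113) and ≈ 0.88 for c
(11.3 vs 10.0, SD 3.2/3.2) — the expected flag count is ~88–89 of 100, so
the criterion cannot be met in the stated world. The test asserts it as
written and is left red for those two parameters (observed 93/100 and
90/100 under the fixed seeds); a, b and the ratio pass at 100/100.

## 7. Numerical choices and degenerate inputs

* Plane/line fits are SVD-based TLS; collinear inputs raise
  degenerate-geometry errors rather than returning arbitrary normals.
* Mesh slicing interpolates each cut edge with a canonical operand order so
  the two faces sharing an edge produce bitwise-identical intersection
  points; without this, contour chaining (which matches endpoints quantized
  at 1e-6 mm) can break a loop under rigid motion.
* Contours below 2 mm perimeter are discarded; vertices exactly on a cut or
  split plane are assigned to the positive (anterior) side.
* Extremum ties anywhere (MLPA, curvature maxima) break toward the smaller
  arc-length / y / z coordinate, making every operator deterministic; all
  randomness in the package flows from explicit seeds.
* Ear-clipping triangulation of the lofted outlines treats points exactly
  on a candidate ear's boundary as blocking, so collinear densification
  points can never be stranded on a degenerate polygon.

## 8. Limitations

* No automatic landmark detection: annotations are inputs.
* The AALP medial border assumes one dominant crease per slice; acromia with
  multiple concave features on the medial arc would keep only the sharpest
  per slice.
* Mesh repair is out of scope; inputs are assumed manifold after the
  reader's duplicate-vertex merge and degenerate-face drop.
* The cohort simulator draws parameters independently (no inter-parameter
  correlation) and sex-pooled, since only pooled summaries are published.
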