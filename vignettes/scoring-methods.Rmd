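---
title: "Deterministic scoring of paper-and-pencil neglect tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic scoring of paper-and-pencil neglect tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neglectscore)
```

## The problem

Unilateral spatial neglect — the loss of awareness for the contralesional
half of space after (usually right-hemisphere) stroke — is routinely
assessed with paper-and-pencil batteries: the patient crosses out printed
targets (short lines, letters E/R among distractors, small stars among
larger ones), marks the midpoints of horizontal lines, and copies template
figures (a four-pointed star; a diamond with a vertical centre line).
Manual scoring of these sheets is slow, and for the copying subtests it
requires qualitative judgments that vary between and within raters, which
in turn moves patients across diagnostic cut-offs.

`neglectscore` replaces the manual step with a deterministic image
pipeline: the same scan always produces the same scores, every scoring
rule is an explicit geometric criterion, and sheets that violate the
assumptions of automated analysis are flagged for manual review rather
than silently mis-scored. No step involves learned models or training
data.

## Pipeline overview

Every sheet passes through the same front end:

1. **Normalization** (`load_and_normalize`). The scan is converted to
   grayscale (luminance for RGB), rescaled to a canonical page width
   (default 1240 px, ~0.169 mm/px for A4), oriented, and deskewed. All
   downstream thresholds are expressed in canonical pixels, so scans of
   any resolution are scored identically.
2. **Ink isolation** (`extract_ink`). The page is binarized with a global
   Otsu threshold capped at `ink_max_intensity`; a rendered mask of the
   printed layout, dilated by `template_dilate` pixels, is subtracted;
   connected components below `min_component_px` are removed as speckle.
   What remains is the patient's ink.
3. **Quality control** (`run_qc`). Deterministic flags reproduce the
   scan-exclusion conditions under which automated analysis is unsafe:
   `low_contrast` (faint-ink pixels the binarizer refused),
   `excessive_noise`, `distorted_print` (poor registration of the printed
   layer), `out_of_region_drawing`, `multiple_bisection_marks`,
   `no_fiducial`.
4. **Subtest scoring** and **battery arithmetic** (below).

### Orientation and deskewing

Skew is estimated by maximizing the concentration (sum of squared bin
masses) of the y-projection of dark pixels over candidate angles in
±5°, followed by parabolic refinement; pages are counter-rotated with
bilinear interpolation. On synthetic scans the residual after correction
is below 0.01°, comfortably inside the 0.5° target. Page orientation uses
the printed arrow fiducial where the layout defines one (the three-line
bisection sheet is needed here: it is nearly 180°-symmetric, which is why
an arrow marks the bottom of that page); other layouts are disambiguated
by the registration score of the printed template under the upright and
upside-down hypotheses. Only scanner-style rotations are handled;
perspective distortion of photographed pages is out of scope.

### Why template subtraction

The printed layout is known exactly (it is shipped as a
`layout_template` and rendered by the same code that generates synthetic
sheets), so subtracting a slightly dilated mask of it is the most direct
way to isolate patient ink. The cost is that ink overlapping the print is
lost; detection windows and thresholds are chosen so that a realistic
strike-through still leaves an unambiguous ink signature (see below). A
documented failure mode is a marking that traces a target's outline so
closely that almost all of it falls inside the dilated mask — such a
target is scored as not crossed.

## Cancellation scoring

Each printed target owns a square detection window (half-widths 40/20/28
px for line crossing, letters, stars). A target is crossed when the
fraction of the window covered by patient ink reaches the per-subtest
threshold (0.012/0.017/0.02). The statistic is monotone in ink — multiple
strokes or zigzags through one target count once, and adding ink can
never un-cross a target. Thresholds were calibrated once on the synthetic
fixtures: on clean renders the observed ink fractions of crossed targets
are at least ~0.021 and of uncrossed targets at most ~0.013 across all
three subtests, so the thresholds sit in the separating gap rather than
at either edge.

Counts are split into left/right by the template's printed side labels;
targets in the middle column (line crossing) and the two pre-crossed
central example stars (star cancellation) never contribute. The layouts
shipped here are an original dialect with the same geometry class as the
clinical sheets: 36 scoreable lines (18 L / 18 R plus 6 ignored middle
targets), 40 letter targets among 155 letters, and 54 scoreable small
stars (27 L / 27 R plus the 2 examples).

## Line bisection

The patient's mark on each of the three lines (top, middle, bottom) is
the ink-weighted x-centroid of the ink crossing a ±30 px band around the
printed line. Ink clusters closer than 50 px merge into one mark; two or
more separated clusters violate the single-midpoint rule and flag the
sheet instead of guessing. Detection on clean synthetic marks is accurate
to well under 1 px.

The signed deviation from the true midpoint maps through nested zones to
3/2/1/0 points. The clinical scoring templates' zone widths are not in
the public domain, so the bands are defined as fractions of the half-line
length — defaults 5% / 12.5% / 25%, i.e. 20/50/100 px (3.4/8.4/16.9 mm)
for the 800 px lines — with inclusive inner boundaries. Both the
fractions and the boundary convention are configurable and documented as
a dialect choice. Direction is `L`/`R` by the sign of the deviation; an
exactly central mark is serialized with no direction letter.

## Figure copying

Corners of the freehand copy are detected on the angular radius profile:
for each 1° of polar angle around the ink centroid, the maximal ink
radius is recorded; after circular smoothing (9° window), local maxima
are outer corners and (for the star) local minima are inner vertices,
each refined to the extreme-radius ink cluster within ±4°. The archetype
is the polygon through the detected corners in angular order — it is
anchored to the drawing, so it translates and scales exactly with it.

Edge presence is evaluated along each archetype edge: the edge is covered
where ink lies within a 9 px corridor, and counts as present when
coverage is at least 85% with no gap longer than 30 px (the closure
tolerance). Angles are not taken from corner positions but from total
least-squares line fits to the ink assigned to each edge (corner clusters
excluded), which measures them to ~0.01° on clean drawings.

**Star.** Shape: all archetype edges present (closed outline) and corner
radii consistent within each class (outer tips, inner vertices; maximum
deviation 100 px from the class mean). Detail: shape passed and exactly 8
corners. Arrangement: horizontal vs vertical tip span difference ≤ 200
px, opposing-tip misalignment ≤ 200 px, consecutive inner-vertex spacing
deviation ≤ 100 px, and all inner-vertex wedge angles within 40° of the
expected 110° with at least two within 30°. The expected angle is
measured at the *inner* vertices: a four-pointed star whose *tip* angles
were 110° would have an inner radius of 0.83 × the outer radius — a
nearly featureless octagon whose radial profile defeats corner detection
and which does not resemble the clinical template — whereas an inner
wedge angle of 110° gives the classic slim silhouette (inner radius
~0.22 × outer). The arrangement criteria are deliberately axis-aligned:
a perfectly drawn star rotated by 45° fails the span/misalignment checks,
which is the intended reading of "correct arrangement". Star arrangement
is evaluated independently of shape and detail (only the diamond has an
explicitly hierarchical variant).

**Diamond.** Shape: all four outer edges present and closed. Detail: a
near-vertical midline whose ink reaches within 40 px of the top and
bottom corners. Arrangement: of the four angles between the fitted
midline and the four fitted outer edges (expected 45°), at most one may
deviate by more than 7°; with no midline the angles are unmeasurable and
arrangement is 0. Both the plain sum and the hierarchical variant
(detail requires shape; arrangement requires both) are reported, along
with the binary completeness criterion (shape AND detail, also used for
the star).

Angle comparisons use a closed tolerance boundary with a measurement
epsilon of 0.05°: fitted angles carry a quantization bias of ~0.002°, and
without the epsilon a drawing rendered exactly at the 7° tolerance would
flip to failing. The epsilon is far below any meaningful clinical
difference.

Degenerate inputs (empty drawing region, fewer than three corners) score
(0, 0, 0) without error.

## Battery arithmetic

Raw scores convert to standard values (0–10 in half-point steps) by
table lookup. The letter-cancellation table implements the published
rule exactly (raw 0–1 → 0, 2–3 → 0.5, …, 40 → 10, i.e.
`floor(raw / 2) / 2`). The official tables for the other subtests are in
the licensed manual; the shipped defaults use the proportional mapping
`floor(raw / raw_max × 20) / 2` and are explicitly editable
configuration — manual owners should substitute the official values via
`sv_table(..., values = )`.

The weighted battery total assigns each subtest a weight equal to its
maximum raw score divided by the summed maxima of the subtests in use.
For the classic subset with maxima {40, 9, 1, 1, 1, 1} this gives
75.47% / 16.98% / 1.89% and a maximum weighted total of 31.79, with the
neglect cut-off scaled proportionally from the full battery (129 of 146,
i.e. 88.36%) to 28.09. Severity bands scale the full-battery cut-offs
(72 / 135 / 166 of 170) to the subset's standard-value maximum: for a
six-subtest battery (maximum 60) the bands are 25.41 / 47.65 / 58.59.
Boundary arithmetic follows the published point values, using raw
fractions rounded half-up at two decimals; the standard-value total sums
exact SVs before any banding. A simple laterality index
`(R − L) / (R + L)` accompanies the counts; the full
center-of-cancellation statistic is out of scope.

## The synthetic-sheet generator

`render_sheet(synthetic_spec(...))` draws the printed layout plus
simulated patient responses and returns the exact ground truth of every
random draw. It emulates the *geometric and statistical* structure the
scorer consumes, not visually realistic handwriting.

* **Crossing behaviour**: target `x` positions map through a logistic
  right-to-left gradient, `p(x) = 1 − s(1 − plogis((x − 0.5)/0.15))`;
  severity `s = 0` crosses everything, `s = 1` drops the leftmost column
  below a 3.5% crossing probability. Strike-throughs are rendered
  roughly perpendicular to line targets and as consistent steep
  diagonals through letters and stars, as real patients produce.
* **Bisection**: offsets are Normal with mean `s × 120` px (rightward
  bias grows with severity) and SD 30 px, truncated to the line.
* **Copies**: the star/diamond archetype with per-vertex angular
  perturbation (SD 1.5° by default), optional per-edge gaps, sinusoidal
  tremor, and an omittable midline or deleted tips.
* **Corruption**: global rotation, salt-and-pepper speckle, and an
  ink-contrast factor, applied after the response layer from a separate
  RNG substream, so toggling corruption never changes which targets were
  crossed.

Defaults were chosen once as plausible clinical magnitudes and are part
of the study conditions for all property suites. What passing tests on
these fixtures shows is that the pipeline implements its rules exactly
and is robust to the modelled corruptions; it does not show robustness to
phenomena the generator does not emulate (crumpled pages, overlapping
corrections, clinician annotations, perspective distortion — precisely
the conditions the QC flags are designed to catch).

## Verification sizes and numerical choices

The shipped test suite verifies, among others: exact recovery of ground
truth counts on 200 clean sheets per cancellation subtest (severities
spanning 0–1), bisection zone and direction agreement with a band-lookup
oracle on 500 sampled offsets (off the band boundaries by a 3 px guard),
the diamond tolerance sweep δ ∈ 0–14° flipping exactly at δ > 7°, star
corner-count and angle-band rules, byte-identical CSV reproduction of a
fixture batch, brute-force oracle equivalence of all agreement statistics
to 1e-10 on small matrices, and Monte-Carlo monotonicity of expected
left-side crossings in severity (1000 seeds per severity step). These
sizes were chosen to exercise the full severity range while keeping the
default suite fast on a single CPU.

Tie-breaks and degenerate cases: zone and angle boundaries are closed
(≤), ink exactly on a window edge counts via the coverage fraction,
all-identical rating matrices return agreement 1 with a warning, and a
zero-variance ICC is reported missing rather than fabricated.

## Agreement statistics

`krippendorff_alpha` (coincidence-matrix formulation; nominal, ordinal
and interval metrics; missing data allowed), `weighted_kappa` (linear
weights by default — the weighting used in the reference comparisons is
not public, so the choice is documented rather than asserted),
`icc_a1` (two-way absolute-agreement single-measure ICC with a
Satterthwaite-style F interval), rank-based AUC, and a bundled
`score_concordance` (exact and ±1 agreement, mean absolute difference,
ICC, kappa, Kendall tau-b via `stats::cor`). All are validated against
independent brute-force implementations in the test suite.

## Known limitations

* The scorer assumes the scan shows one completed sheet of a known
  layout; it does not segment multiple sheets per page.
* Ink that coincides almost entirely with printed material is invisible
  to template subtraction.
* Only affine scanner skew is corrected.
* The default standard-value tables outside letter cancellation are
  proportional stand-ins, not the licensed clinical tables.
* Corner detection assumes a single connected-ish drawing per region;
  widely scattered fragments shift the centroid and degrade corner
  classification (such sheets typically also trip QC flags).
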