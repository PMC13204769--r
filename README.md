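# neglectscore

Deterministic, reproducible scoring of the paper-and-pencil subtests used
to diagnose unilateral spatial neglect — the post-stroke loss of awareness
for one half of space. Scanned test sheets go in; per-subtest scores,
standard values, weighted battery totals and diagnostic categories come
out, with every scoring rule implemented as an explicit geometric
criterion (no learned models), so the same scan always yields the same
result.

Intended users are clinical neuropsychologists and researchers who score
cancellation, line-bisection and figure-copying protocols, and
methodologists studying rater variability in those scores.

## What it scores

| Subtest | Raw score | Extras |
|---|---|---|
| Line crossing | crossed-out lines (36 scoreable) | left/right split; middle column ignored |
| Letter cancellation | crossed E/R targets (max 40) | left/right split |
| Star cancellation | crossed small stars (max 54) | central example stars excluded |
| Line bisection | 3/2/1/0 points per line, 3 lines (max 9) | per-line deviation and L/R direction |
| Star copying | shape + detail + arrangement (0–3) | binary completeness criterion |
| Diamond copying | shape + detail + arrangement (0–3) | hierarchical variant, binary criterion |

The pipeline per sheet: grayscale + rescale to a canonical width →
orientation by printed arrow fiducial or template registration → deskew
(projection-profile search, residual < 0.01° on clean scans) → global
Otsu binarization → subtraction of the rendered printed layout → speckle
cleanup → subtest-specific scoring. Quality-control flags
(`low_contrast`, `excessive_noise`, `distorted_print`,
`out_of_region_drawing`, `multiple_bisection_marks`, `no_fiducial`) route
problematic sheets to manual review instead of guessing.

Battery arithmetic follows the published conversion rules: letter
cancellation standard values by the 0.5-step table (raw 40 → SV 10),
subtest weights `max_s / Σ max` (75.47% / 16.98% / 1.89% for the classic
subset {40, 9, 1, 1, 1, 1}, maximum weighted total 31.79, neglect cut-off
28.09 = 88.36%), and severity bands scaled from the 170-point battery
(25.41 / 47.65 / 58.59 for a 60-point standard-value subset).

A seeded synthetic-sheet generator (`synthetic_spec()` / `render_sheet()`)
produces printed layouts plus simulated patient ink — a logistic
right-to-left crossing gradient controlled by a severity parameter,
biased bisection marks, distorted copies (angle perturbation, gaps,
tremor) and scan corruption (rotation, speckle, faint ink) — together
with exact ground truth, so the whole system is testable without
clinical data or copyrighted test materials. Agreement statistics
(Krippendorff's alpha, weighted Cohen's kappa, ICC(A,1) with CI,
Kendall tau-b, sensitivity/specificity/AUC) support validation studies.

## Worked example

Simulate a moderately neglecting patient's star-cancellation sheet and
score it end to end:

```r
library(neglectscore)

sp <- synthetic_spec("star_cancellation", severity = 0.6, seed = 42)
sh <- render_sheet(sp)              # sheet image + exact ground truth
sc <- score_sheet(sh$sheet, sh$template)
print(sc$result)
#> <star_cancellation: L 11 + R 23 = 34 crossed, SV 6.0>
print(sh$truth)
#> <ground_truth star_cancellation (seed 42, severity 0.60)>
#>   crossed: L 11, R 23, total 34
laterality_index(sc$result$left_count, sc$result$right_count)
#> [1] 0.3529412
```

The scorer recovered the generated truth exactly: 11 of 27 left-side and
23 of 27 right-side stars crossed (raw total 34 → standard value 6.0 of
10). The positive laterality index (+0.35) quantifies the rightward bias
— left-sided omissions, the classic neglect pattern. `run_batch()` scores
a directory of scans against a `manifest.csv` into one CSV row per
patient (columns `LineC_LS, LineC_RS, LineC, LineC_SV, …,
CopyD_NET_hierarchical` plus weighted totals and diagnoses), and
`render_overlay()` writes the color-annotated sheets (green = detected
crossing, red = miss, yellow = excluded, red archetype over the copied
figure). A command-line wrapper with `score-batch`, `score-single`,
`make-synthetic` and `compare-scores` subcommands is installed at
`inst/cli/neglectscore.R`.

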