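---
title: "Methods: anti-leakage image transformation and reader-study statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anti-leakage image transformation and reader-study statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trichobench)
```

trichobench implements the computational core of a head-to-head diagnostic
reader study on trichoscopic (scalp dermoscopy) images: dermatologists of
several experience levels and general-purpose multimodal language models
read the same cases, each giving a suspected diagnosis (SD) and up to three
differential diagnoses (DD). This vignette explains the models and
procedures the package implements, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the design choices
made where more than one reasonable construction existed.

## The anti-leakage problem and the transformation pipeline

Large pretrained vision-language models have very likely seen many publicly
available dermatology images during training. Evaluating such a model on
unaltered public images therefore confounds diagnostic ability with
memorization: an image (or a near-duplicate) may simply be *recognized*.
The pipeline in `transform_image()` addresses this by applying a fixed
sequence of ten subtle transformations that changes low-level pixel
statistics — the signal near-duplicate retrieval and memorization rely on —
while leaving the morphology a human reader uses (hair-shaft contours,
follicular openings, scaling, erythema) intact:

1. **Border crop** — `round(0.0075 × dim)` pixels per side, per axis
   (removes ruler marks, vignetting and frame artifacts).
2. **White padding** — `round(0.015 × dim)` pixels per side (shifts the
   composition).
3. **Rescaling** — a factor drawn uniformly from 0.90–1.10 (bilinear; the
   canvas resizes).
4. **Rotation** — an angle drawn from −3° to +3° about the centre (canvas
   preserved, corners filled with the pad color so they blend with the
   padding frame).
5. **Brightness** — multiplicative factor in 1.01–1.04.
6. **Contrast** — factor in 1.01–1.04, pivoting on the *per-image mean*
   rather than mid-gray, so a factor near 1 is a near-identity at any
   exposure.
7. **Saturation** — factor in 1.005–1.01, scaling chroma about the
   per-pixel Rec. 601 luma.
8. **Gamma** — exponent in 0.8–1.2, `v ← 255 (v/255)^(1/γ)`.
9. **Gaussian blur** — kernel size 3 (`σ = 0.3((k−1)/2 − 1) + 0.8 = 0.8`),
   symmetric border reflection.
10. **Gaussian noise and a smoothed perturbation** — independent per-pixel
    noise (sd 2 intensity units), then a white-noise field smoothed with a
    Gaussian of sd 8 px and rescaled to a maximum absolute value of
    3 units, added to all channels.

Every random parameter is drawn from a single integer seed and recorded in
a `TransformRecord`; re-running with the same seed reproduces the output
byte-for-byte (`transform_batch()` derives per-image seeds by stable
hashing of `(master_seed, image_id)`, so adding images never shifts
existing outputs). Photometric steps run in double precision, clip to
[0, 255] after each step, and round once at the end of the stage.

Numerical conventions worth stating explicitly, since each had at least one
alternative: fractional pixel counts round half away from zero, per side,
per axis; interpolation is bilinear for both rescaling and rotation;
scaling changes the canvas while rotation preserves it; blur and field
smoothing reflect the border symmetrically (edge pixel repeated); the
amplitudes of the two stochastic stages default to values that keep the
mean absolute pixel change below 2% of the dynamic range. Brightness and
contrast act on raw channel values, not a perceptual space — with factors
this close to 1 the difference is negligible, and raw-channel semantics
keep every stage an exact, testable arithmetic statement.

## Quantitative integrity verification

The contract the pipeline must satisfy — *unrecognizable to a pretrained
model, still diagnosable by a clinician* — is made quantitative in
`verify_pair()` by two opposing metrics:

* **Preserve**: the mean local SSIM (7×7 Gaussian window, σ 1.5,
  K₁ = 0.01, K₂ = 0.03, dynamic range 255, computed on rounded Rec. 601
  luma) between original and transformed image must be at least
  `threshold_preserve`.
* **Disrupt**: at least one perceptual-hash Hamming distance — average
  hash (8×8 box-average, strictly-greater-than-mean bits) or difference
  hash (8×9, left-greater-than-right bits) — must be at least
  `threshold_disrupt` bits (default 1), so exact or near-duplicate lookup
  against a memorized copy fails.

The preserve threshold defaults to 0.60, calibrated by running the default
pipeline on 20 seeded synthetic scalp images: observed SSIM ranged
0.64–0.83, while an unrelated noise image scores ≈ 0 against any original,
so 0.60 separates "same structure, perturbed" from "different image" with
margin on both sides. Note that the synthetic images are a harsh test:
their hard-edged, non-anti-aliased strokes concentrate energy at exactly
the high frequencies that blur, noise and resampling disturb most, so real
dermoscopy photographs — dominated by smooth gradients — score higher under
the identical pipeline. These automated metrics stand in for the human
expert review a clinical study would use; they check structural fidelity,
not diagnosability, which is a declared substitution and a limitation.

## Scoring

A response is correct under **SD** if the canonicalized suspected diagnosis
equals the canonicalized truth, and under **SD+DD** if the truth appears
among the suspected plus up to three differential diagnoses. It follows
cell-wise that SD-correct implies SD+DD-correct, a property the test suite
asserts over random response sets. Label matching is exact after
normalization (lower-casing, whitespace/punctuation collapsing) and an
editable synonym vocabulary (`inst/extdata/vocabulary.csv` ships an example
for common trichologic diagnoses); no fuzzy matching is attempted, because
adjudicating near-miss diagnoses (a subtype versus its parent entity)
is a clinical judgment that belongs in the vocabulary file, visible and
auditable, not inside a string-distance heuristic.

## Accuracy, intervals and comparisons

Diagnostic accuracy is the proportion of correct responses over all
non-missing (rater, case) evaluations of a group. Confidence intervals are
**Wilson score** intervals: with \(\hat p = k/n\) and \(z\) the normal
quantile,

\[
\frac{\hat p + z^2/2n}{1 + z^2/n} \;\pm\;
\frac{z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n},
\]

which is well behaved at the small \(n\) (24–25 evaluations per AI model)
and extreme proportions (8%) this design produces. The Wilson interval
reproduces, to the printed decimal, every interval of the reference
accuracy table that the package rebuilds from count margins — which is how
the method was identified, since the source study names only "95% CI". One
cell disagrees in the last digit (the pooled dermatologist SD lower bound
prints 53.0 where 218/375 gives 53.08 → 53.1), consistent with a rounding
slip in the source rather than a different interval.

Groups are compared on the correct/incorrect × group table with Pearson's
chi-square (no continuity correction); when any expected cell count falls
below 5 (Cochran's rule, the usual operationalization of "when
appropriate"), Fisher's exact test replaces it — exact for two groups, a
seeded 10⁵-table Monte-Carlo estimate for more. If the omnibus p-value is
below α = 0.05, all pairwise 2×2 tests run under the same selection rule
and are Holm-Bonferroni adjusted. Evaluations are treated as independent
throughout; responses of one rater across cases (and of raters within a
case) are in truth correlated, so these tests are anti-conservative to an
unknown degree. That matches the analysis style of the study being
reproduced and is flagged here as a statistical limitation, not a
recommendation.

## Agreement: Gwet's AC1

Inter-rater reliability on the binary correct/incorrect ratings uses
Gwet's AC1, which remains stable where Cohen/Fleiss kappa collapses under
skewed prevalence (a real concern here: some cases are answered correctly
by nearly everyone). For item \(i\) with \(r_i \ge 2\) ratings of which
\(r_{i1}\) are "correct":

\[
a_i = \frac{\sum_k r_{ik}(r_{ik}-1)}{r_i(r_i-1)}, \quad
p_a = \overline{a_i}, \quad
\pi = \overline{r_{i1}/r_i}, \quad
p_e = 2\pi(1-\pi), \quad
AC_1 = \frac{p_a - p_e}{1 - p_e}.
\]

Items rated by fewer than two raters are excluded. The standard error is a
leave-one-item-out jackknife — chosen over the closed-form variance because
it is assumption-light, handles unequal \(r_i\) from missing cells without
special cases, and is directly testable (duplicating every item must
shrink it by \(\approx 1/\sqrt2\), which the suite checks); the closed form
could be added behind the same interface. The CI is \(AC_1 \pm z\,SE\)
truncated to [−1, 1], and values map to the conventional six bands (poor /
slight / fair / moderate / good / very good, upper bounds inclusive).

"Between groups" agreement is not uniquely defined for multi-rater groups;
`between_group_agreement()` implements a declared interpretation: each
group collapses to one pseudo-rater carrying its per-case majority vote
(ties count as incorrect), and AC1 runs across pseudo-raters. Outputs are
labelled with this construction, and its results cannot be validated
against the source study without the unpublished raw matrix.

## Synthetic data: what it emulates, and what it does not

Because the study's images and raw responses are unpublished, the package
generates both.

**Images** (`generate_scalp_image()`): a uniform skin-toned background,
hair shafts as quadratic Bézier strokes stamped with hard circular brushes,
follicular dots as filled circles, optional larger patches for scale or
erythema. Anti-aliasing is deliberately off so that brute-force oracles
(connected-component counts, exact pixel predicates) are exact. These
images have countable, localized diagnostic structure — which is what the
pipeline must preserve — but none of the texture, specular reflection,
depth-of-field or disease-specific pattern taxonomy (yellow dots,
exclamation-mark hairs) of real trichoscopy. Passing tests therefore show
that the pipeline preserves *drawn morphology under known ground truth*,
not that any particular clinical feature survives.

**Responses** (`simulate_responses()`): each present (rater, case) cell is
Bernoulli with success probability `plogis(group_logit + case_offset)`;
case offsets are drawn once per case from N(0, `case_difficulty_sd`²) and
shared by all raters. Difficulty entering on the log-odds scale is the
simplest structure that produces the between-case heterogeneity AC1 is
sensitive to: shared hard cases push raters into agreement beyond what
their marginal accuracies imply. The default design mirrors the reference
study — groups of 5/4/6 dermatologists, four single-model AI raters,
25 cases, and one missing evaluation for one AI rater. The case count and
the missing cell are not stated in the source; both are inferred from its
printed evaluation totals (16.0% is 4/25; 33.3% is 8/24) and are
overridable in `study_design()`. The default response model's group
log-odds (residents 0.0, board-certified 0.1, experts 1.0; AI models −2.5
to −0.7 for SD) reproduce the accuracy *ordering* of real reader panels,
with `case_difficulty_sd = 1` giving a realistic spread of case-level
accuracies; they make no claim to calibrate any particular model.

**Margins** (`matrix_from_margins()`): for exact reproduction of published
accuracy tables, a deterministic matrix is built whose per-group or
per-rater correct counts equal counts recovered from printed percentages;
correct cells fill case-major from the lowest case index. Accuracy,
Wilson intervals and omnibus chi-square tests depend on the data only
through these margins, so `reproduce_margins()` recovers the published
percentages, intervals and significance conclusions exactly. Agreement
statistics do *not* depend only on margins, which is why the source
study's AC1 values are not reproduction targets.

One printed-table inconsistency is carried openly: the expert group's
SD+DD accuracy prints as 80.3%, but no integer count over 150 evaluations
yields that value, and the pooled dermatologist count (68.3% of 375 = 256)
forces 120/150 = 80.0%. `reference_margins()` carries 120/150 and documents
the discrepancy.

## Problem sizes and reproducibility

The bundled end-to-end demo (`run_study()`) uses 160×160-pixel synthetic
images and the 19-rater × 25-case design; the property suites use up to
1,000 seeded parameter draws, a 2,000-replicate null calibration of the
group comparison, exhaustive Fisher enumeration over small tables, and
grid inversion of the score test at 10⁻⁴ resolution — sizes chosen so the
whole suite runs in about a minute on a single core while keeping
Monte-Carlo standard errors well inside the asserted tolerances. Every
stochastic component takes an explicit integer seed, and all batch
operations derive per-item seeds by stable hashing, so every table, image
and report in a study bundle is byte-reproducible from its manifest.

## Known limitations

* Integrity metrics (SSIM, perceptual hashes) are proxies: they bound
  pixel-statistical disruption and structural drift, not clinical
  diagnosability, and they do not probe any actual model's recognition.
* Independence assumptions in the chi-square/Fisher comparisons ignore
  rater and case clustering.
* The synthetic images are schematic; results on them bound pipeline
  behaviour on real dermoscopy only qualitatively.
* The AC1 confidence intervals of the source study cannot be checked
  without its raw response matrix; only the statistic's definition and its
  internal properties are verified.
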