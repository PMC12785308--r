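# trichobench

Toolkit for head-to-head diagnostic **reader studies on trichoscopic
(scalp dermoscopy) images**, built for the setting where human readers
(dermatology residents, board-certified dermatologists, trichology
experts) and general-purpose multimodal AI models diagnose the same cases
from images alone.

It addresses two problems such studies face:

1. **Dataset leakage.** Public dermatology images have plausibly been seen
   by large pretrained models; evaluating on them unaltered confounds
   diagnosis with memorization. trichobench provides a seeded, fully
   reproducible ten-stage transformation pipeline (crop, pad, rescale,
   rotate, brightness, contrast, saturation, gamma, blur, noise, smoothed
   perturbation) that disrupts the low-level statistics near-duplicate
   recognition relies on while preserving diagnostic morphology, plus
   quantitative integrity verification of every transformed image (SSIM
   for structure preserved, perceptual-hash Hamming distance for
   fingerprint disrupted).
2. **Reader-study statistics.** Responses (a suspected diagnosis, SD, and
   up to three differential diagnoses, DD) are scored against ground truth
   under the SD and SD+DD rules; accuracy is estimated per group with
   **Wilson score** 95% intervals; groups are compared with Pearson's
   chi-square or Fisher's exact test (Cochran's rule) with
   **Holm-Bonferroni** post hoc adjustment; inter-rater reliability uses
   **Gwet's AC1** for binary ratings, with jackknife standard errors,
   handling missing evaluations.

For a proportion k/n, the Wilson interval is
((p̂ + z²/2n) ± z·√(p̂(1−p̂)/n + z²/4n²)) / (1 + z²/n), and for items with
rᵢ ≥ 2 ratings, AC1 = (p_a − p_e)/(1 − p_e) with p_e = 2π(1−π), p_a the
mean within-item agreement and π the mean prevalence of "correct".

Because the motivating study's images and raw responses are unpublished,
the package also ships first-class synthetic generators: scalp-like images
with known ground-truth structures (hair-shaft strokes, follicular dots,
patches) and simulated rater responses with group-level accuracy and
shared per-case difficulty — enough to exercise and test every stage end
to end. See `vignettes/reader-study-methods.Rmd` for the full methods
account.

## Worked example

Rebuild the accuracy analysis of the bundled reference reader study (15
dermatologists in three groups, four AI models, 25 trichoscopic cases)
from its published count margins:

```r
library(trichobench)
rep <- reproduce_margins()
subset(rep$accuracy, mode == "SD")
#>            group mode   k   n   pct  ci_lo ci_hi
#>   dermatologists   SD 218 375 58.13 53.082 63.02
#>               ai   SD  18  99 18.18 11.822 26.92
#>         resident   SD  61 125 48.80 40.205 57.47
#>  board_certified   SD  51 100 51.00 41.348 60.58
#>           expert   SD 106 150 70.67 62.938 77.36
#>          chatgpt   SD   4  25 16.00  6.403 34.65
#>             grok   SD   4  25 16.00  6.403 34.65
#>           gemini   SD   8  24 33.33 17.972 53.29
#>           claude   SD   2  25  8.00  2.222 24.97
```

Dermatologists identified the correct primary diagnosis in 58.1% of
evaluations (95% CI 53.1–63.0) against 18.2% (11.8–26.9) for the pooled AI
models; `rep$comparisons` shows the difference is significant
(chi-square p = 1.5e-12), while the four AI models differ for SD+DD
(p = 0.042) but not SD. Individual building blocks are exported:

```r
round(100 * wilson_ci(8, 24), 1)   # Gemini SD: 8 correct of 24
#> lower upper
#>  18.0  53.3

m <- correctness_matrix(rbind(c(1, 1, 0, 0),
                              c(1, 0, 0, 0)), c("r1", "r2"))
gwet_ac1(m)
#> Gwet's AC1 = 0.529 (95% CI -0.395, 1.000) - moderate agreement
#> p_a = 0.750, prevalence = 0.375, p_e = 0.469; 4 items, 2 raters
```

An end-to-end simulated study — synthetic images, transformation,
integrity checks, simulated responses, accuracy/comparison/agreement
tables, manifest and log — runs with:

```r
res <- run_study(default_study_config(output_dir = "demo_run", master_seed = 1))
```

and is byte-reproducible from its seed. A thin CLI over the same functions
lives at `inst/scripts/trichobench.R`
(`simulate-images`, `transform`, `verify`, `report`, `reference-margins`).

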