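---
title: "Quantifying facial erythema with co-occurrence texture features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying facial erythema with co-occurrence texture features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glcmface)
```

## The measurement problem

Persistent facial erythema — the hallmark of erythematotelangiectatic
rosacea — is usually graded on the Clinician Erythema Assessment (CEA), a
five-level ordinal scale (0 = none … 4 = severe) assigned by a trained
dermatologist. Ordinal clinical scales are practical but coarse and
subjective: independent raters disagree on a substantial fraction of
assessments. An objective complement is texture analysis of standardized
cross-polarized photographs, in which erythematous and vascular lesions
appear as irregular darkened structure against smooth healthy skin.

`glcmface` implements that complement end to end: grey-level co-occurrence
matrix (GLCM) texture scoring of masked facial regions, weighted whole-face
aggregation, and the nonparametric longitudinal statistics that connect the
instrumental scores to clinician grading across the three timepoints of a
phototherapy study (T0 baseline, T1 four weeks after three treatments, T2
three months after three treatments).

## The texture model

For an 8-bit greyscale image and a region of interest (ROI), the GLCM
tallies how often a pixel of grey level $i$ has a right-hand neighbour of
level $j$ at distance $d = 1$ (angle $0^\circ$). With $P(i,j)$ the
normalized co-occurrence probability over $256 \times 256$ levels, the two
features are

$$\mathrm{contrast} = \sum_{i,j} P(i,j)\,(i-j)^2, \qquad
  \mathrm{homogeneity} = \sum_{i,j} \frac{P(i,j)}{1 + |i-j|}.$$

Contrast is the mean squared grey-level jump between horizontal neighbours:
it rises with lesional irregularity. Homogeneity concentrates mass near the
diagonal and lies in $(0, 1]$; it equals 1 exactly when contrast is 0
(every co-occurring pair has $i = j$). Some presentations print the
homogeneity denominator as $1 + i - j$; only the absolute-difference form
keeps the feature positive and bounded, so that is what is implemented.

Four decisions close gaps that the usual verbal description leaves open:

* **Asymmetric tally.** Pairs are counted once, left to right, matching the
  worked single-offset construction; `compute_glcm(symmetric = TRUE)` is
  available but off by default. Features are computed on the normalized
  grid, so symmetrisation changes nothing when the underlying field is
  statistically left-right symmetric.
* **Mask handling.** A pair contributes only if *both* pixels are inside
  the ROI; boundary-straddling pairs are dropped.
* **No re-quantisation.** Grey levels stay at 256. Several toolkits default
  to 8 levels, which changes the features by orders of magnitude; that is
  explicitly rejected.
* **Degenerate ROIs** (no valid horizontal pair) raise an error naming the
  zone — never a silent zero.

Whole-face scores are weighted sums over the four clinically delineated
zones, cheeks weighted 0.35 each, nose and chin 0.15 each:

$$X_{\text{face}} = 0.35\,X_{LC} + 0.35\,X_{RC} + 0.15\,X_{N} + 0.15\,X_{C}.$$

The weights are configurable but must sum to 1. Note that a weighted sum of
per-zone *medians* is not the median of per-subject weighted sums; the
pipeline always aggregates per subject first.

## The statistical layer

All inference is nonparametric (the feature distributions at clinical scale
fail normality screening, available as `normality_screen()`):

* **Friedman rank test** across the three timepoints, with the Conover tie
  correction (mid-ranks within each subject); `stats::friedman.test` is
  used as an independent oracle in the test suite.
* **Dunn post hoc** pairwise z-tests on mean ranks for T0–T1, T0–T2, T1–T2.
  The multiplicity correction is not specified by the usual description of
  the method; Bonferroni over the three comparisons is used (conservative,
  standard).
* **Spearman correlation** of the mean CEA grade with the face-level
  features, with $t = R\sqrt{N-2}/\sqrt{1-R^2}$ against $t(N-2)$ — the
  convention of clinical correlation tables. Mid-ranks are used on ties.
* **Percent changes** are computed from unrounded medians and rounded to
  two decimals only at presentation. Published tables of this kind often
  carry small internal rounding inconsistencies (percent changes computed
  from unrounded intermediates); the raw formula is authoritative here.
* **Complete agreement** is the fraction of assessments on which all three
  raters coincide exactly. Richer agreement statistics (kappa, ICC) are
  deliberately out of scope for v1.

Significance is declared at $p < 0.05$ (configurable `alpha`).

One reference value deserves a flag: a published summary of this design
reports a median CEA drop "by 61.11% from 3.10 to 1.30", but
$100\,(3.10-1.30)/3.10 = 58.06\%$; the printed figure evidently refers to
means rather than medians. The arithmetic self-checks
(`reproduce_arithmetic()`) therefore only include percent changes that are
internally consistent with their printed endpoints.

## What the simulator emulates — and what it does not

No clinical photographs are redistributable, so validity is established on
a synthetic study (`sim_config()`, `generate_study()`,
`simulate_features()`) whose defaults state the emulated world once:

* **20 subjects × 3 timepoints**, 512 × 512 px images, three raters.
* **Skin** is a smooth bright field (level 180) with low-frequency shading.
* **Erythema** appears as Gaussian darkened blobs (2–6 per zone, baseline
  depth 40 grey levels, radius `image_size/64` px) — in cross-polarized
  greyscale, red lesions absorb in the green channel that dominates
  luminance, so depth of darkening is the severity proxy.
* **Telangiectasia** are thin dark random-walk streaks on the cheeks
  (3 per cheek, depth 0.75 × lesion depth). They are the dominant
  fine-texture driver, which mirrors the physics: vessels are the sharp
  structure that co-occurrence contrast responds to.
* **Treatment** multiplies every lesion amplitude by `effect_T1 = 0.4` at
  T1 and `effect_T2 = 0.4` at T2 — a strong response that persists, the
  pattern the method is meant to detect. Masks and lesion geometry are
  fixed per subject; only amplitudes move.
* **Sensor noise** is i.i.d. Gaussian, `noise_sd = 1.5` grey levels. The
  choice is deliberate: independent pixel noise contributes a floor of
  $2\sigma^2$ to contrast, and 1.5 puts that floor (≈ 4.5) below the
  lesional signal so treatment effects dominate. No quantitative noise
  characterisation of the original imaging chain is available; this is a
  free calibration stated once.
* **Raters** follow the minimal model producing imperfect agreement:
  `grade = clamp(round(0.3 · severity + bias + noise), 0, 4)` with
  per-rater bias SD 0.15 and per-assessment noise SD 0.2, calibrated so the
  panel agrees completely on roughly half to two-thirds of assessments —
  the realistic regime for a five-level scale.
* **Determinism**: every random draw flows from one master seed through
  stable per-(subject, timepoint, purpose) substreams, so a study directory
  is byte-identical across runs.

True severity is defined as the mean grey-level depression of the noiseless
lesion field over each zone mask, aggregated with the face weights. Because
zone geometry and lesion scale are proportional to `image_size`, severity
and its calibration are approximately scale-invariant, which is what lets
the heavy validation runs use 64–96 px images instead of 512 px without
changing the stated world.

The simulator does **not** attempt photorealism: no colour, no specular or
sebaceous structure, no papules/pustules or phymatous change, no
registration error between visits. A green synthetic test therefore
establishes that the pipeline recovers known severity orderings and
respects its null — not that any particular clinical effect size would be
reproduced on real photographs.

## Numerical choices

* Probability grids must sum to 1 within $10^{-9}$; feature tests compare
  at $10^{-9}$ relative.
* Greyscale conversion of RGB input is Rec. 601 luminance
  ($0.299R + 0.587G + 0.114B$), rounded half-up — the original conversion
  is unstated, so one standard is fixed for reproducibility.
* Ranks use midpoints on ties everywhere (Spearman and Friedman).
* Sample standard deviations use the $n-1$ denominator (verified against
  the packaged treatment-energy table's printed summaries).
* `|R| = 1` Spearman cases report $t = \pm\infty$, $p = 0$ rather than
  failing; constant vectors are an explicit error.
* A fully tied Friedman table reports statistic 0, $p = 1$.

## Known limitations

* Only the horizontal offset $d = 1$, $\theta = 0^\circ$ is implemented —
  the configuration the whole-face scores are defined for. Multi-angle
  averaging and the wider Haralick set are out of scope.
* TIFF input is not supported in this build (no TIFF reader in the
  dependency footprint); images and masks are PNG.
* ROI placement is consumed from mask files; there is no interactive
  delineation or automatic face detection.
* The reported Spearman $t$ values in published correlation tables are
  computed from unrounded $R$; recomputing $t$ from a printed
  three-decimal $R$ agrees only to about half a percent, so exact
  reproduction of printed $t$ is impossible by construction.
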