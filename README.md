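# glcmface

Objective quantification of facial erythema from cross-polarized
photographs, for longitudinal dermatology studies (e.g. intense-pulsed-light
treatment of rosacea) where clinician grading on the ordinal CEA scale
(0 = none … 4 = severe) needs an instrumental counterpart.

## What it computes

For each photograph and each of four manually delineated regions of
interest (left cheek, right cheek, nose, chin), the package builds a
256 × 256 grey-level co-occurrence matrix at horizontal offset d = 1
(θ = 0°) and computes the two Haralick-style features

    contrast    = Σ_{i,j} P(i,j) (i − j)²
    homogeneity = Σ_{i,j} P(i,j) / (1 + |i − j|)

where `P(i,j)` is the normalized probability that a pixel of grey level `i`
has a right-hand neighbour of level `j`. Contrast rises with irregular,
lesional texture; homogeneity (in (0, 1]) rises as skin becomes uniform.
Whole-face scores weight the zones 0.35/0.35/0.15/0.15
(left cheek / right cheek / nose / chin).

On top of the features sits the full clinical statistics layer:
mean-of-raters CEA scores and complete-agreement analysis, per-session
treatment-energy summaries, Friedman rank tests (tie-corrected) with Dunn
post hoc pairwise comparisons across the three study timepoints
(T0 baseline, T1 four weeks after three treatments, T2 three months after),
Spearman correlation of mean CEA with the face-level features
(t(N − 2) inference), and percent-change summaries of medians.

Because clinical photographs cannot be redistributed, the package includes
a deterministic synthetic-study generator: face images with spatially
clustered Gaussian erythema blobs and thin dark telangiectasia streaks
whose amplitudes shrink under treatment, fixed per-subject ROI masks, and a
noisy three-rater grading model. Every module is exercised end to end on
this generator; see `vignettes/methods.Rmd` for what the simulation does
and does not establish.

## Worked example

```r
library(glcmface)

cfg   <- sim_config(n_subjects = 6, image_size = 96, seed = 3)
study <- simulate_features(cfg)          # render + extract, in memory
res   <- study_analysis(study$features, study$cea)
print(res)
```

```
glcmface study analysis (alpha = 0.05 )
  left_cheek.contrast      medians 52.315/12.063/12.728 | T0->T1 +76.94% T0->T2 +75.67% | Friedman p = 0.0094
  ...
  face.contrast            medians 57.139/13.144/12.933 | T0->T1 +77.00% T0->T2 +77.37% | Friedman p = 0.0057
  face.homogeneity         medians 0.323/0.398/0.394 | T0->T1 +23.11% T0->T2 +21.99% | Friedman p = 0.0094
  complete agreement: 8/18 (44.4%)
  mean CEA vs face features (Spearman):
 timepoint     feature N      R     t       p
        T0    contrast 6  0.941  5.57 0.00510
        T0 homogeneity 6 -0.880 -3.71 0.02060
        ...
```

Reading it: per zone and for the whole face, the median contrast drops and
homogeneity rises from baseline (T0) to both post-treatment visits, with
significant Friedman tests — the simulated treatment (amplitude factor 0.4)
is recovered. The three synthetic raters agree completely on 8 of 18
assessments, and the mean CEA grade correlates strongly and positively with
face contrast (negatively with homogeneity), the signature the method is
designed to exhibit.

The same pipeline runs from the command line on files:

```sh
Rscript exec/glcmface simulate --out study/ --seed 7 --n-subjects 20
Rscript exec/glcmface extract  --manifest study/manifest.csv --out features.csv
Rscript exec/glcmface analyze  --features features.csv --cea study/cea.csv --out report
Rscript exec/glcmface reproduce-arithmetic   # packaged arithmetic self-checks
```

`analyze` writes a diffable Markdown report plus a machine-readable JSON
bundle; `reproduce-arithmetic` recomputes the packaged printed-value checks
(treatment-energy means ± SD, internally consistent percent changes of
published medians, 39/60 = 65% complete agreement) and exits nonzero on any
mismatch.

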