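---
title: "Grading diabetic retinopathy from block histogram features"
author: "FundusRank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading diabetic retinopathy from block histogram features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FundusRank)
```

## The problem

Diabetic retinopathy (DR) damages the retina progressively; its severity is
graded from fundus photographs, largely by the burden of lesions such as hard
exudates — bright lipid deposits that appear as high-intensity blobs against
the darker retinal background. FundusRank implements a pipeline that turns an
8-bit fundus image into a severity grade through four stages:

1. **Windowing.** The image is tiled into non-overlapping sliding-window
   blocks of `windowSize` pixels per side (edge blocks truncated, never
   padded, so no fabricated intensities enter any histogram).
2. **Boundary histograms and group sparsity.** Each block's pixels are
   binned into `sMax` equal-width intensity bins. The counts are normalised
   twice — by the left-boundary constant $N/(s_{\max}+1)$ and the
   right-boundary constant $N/(s_{\max}-1)$, where $N$ is the block's pixel
   count — and the two normalised histograms are summed. The block's
   *group-sparsity* value is the sum of squares of the combined histogram,
   $\mathrm{GS} = \sum_k S_k^2$. GS is maximal for a block whose pixels share
   one bin and drops when mass spreads over bins, so it flags blocks that
   straddle a lesion boundary.
3. **Severity distance.** A candidate-lesion intensity distribution
   $(\mu_1, \sigma_1)$ of the test image is compared with a healthy reference
   $(\mu_2, \sigma_2)$ through the closed-form Gaussian overlap distance
   $$D = 1 - \sqrt{\frac{2\sigma_1\sigma_2}{\sigma_1^2+\sigma_2^2}}\,
   \exp\!\left(-\tfrac14\frac{(\mu_1-\mu_2)^2}{\sigma_1^2+\sigma_2^2}\right),$$
   which is one minus the Hellinger affinity of the two normal densities: it
   lies in $[0,1)$, is symmetric, vanishes exactly at equality, and grows
   with both the spread of disease (mean separation) and its depth
   (spread mismatch). A numerical-quadrature oracle in the test suite
   verifies the closed form independently.
4. **Ranking.** Either the distance is thresholded into ordinal grades, or a
   one-vs-rest support-vector model is trained on the per-block GS vectors.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `windowSize` | 8 | px | blocks comparable to small-exudate diameter; Table-style sweeps over 1–8 are supported by `runExperiment()` |
| `sMax` | 2 | bins | a bright/dark split at intensity 128; see below |
| `fraction` | 0.1 | — | share of in-field blocks kept (by GS rank, tie-inclusive) when selecting candidate-lesion pixels |
| `topBins` | 1 | bins | pooled top occupied intensity bins of the selected blocks |
| `fovFloor` | 32 | intensity | blocks with mean below this are treated as the camera surround and ignored |
| `sigmaFloor` | 0.5 | intensity | clamp preventing a degenerate $\sigma = 0$ |
| `thresholds` | 0.1, 0.25, 0.45, 0.7 | — | discretise $D$ into grades 0–4; configuration, not science |
| SVM `cost` | 1.0 | — | soft-margin cost of each one-vs-rest machine |

**Why `sMax = 2`.** The group-sparsity statistic sums squared histogram
entries over bins, so it records *how mixed* a block is but not *which*
intensities mix. With fine binning, grade-irrelevant structure — vessels,
background texture, illumination sitting near a bin edge — contributes
exactly the kind of mixedness that lesions do, and the lesion signal drowns.
With two bins split at mid-range, everything darker than 128 (background,
vessels, surround) collapses into one bin and only bright pathology
(exudates, the optic disc) can create mixed blocks. Finer binning remains
available and is exercised throughout the test suite; it is the right choice
when the pathology of interest is *not* a bright-vs-dark phenomenon.

**The candidate-lesion bridge.** The distance stage needs $(\mu, \sigma)$
pairs measured from images. The package derives them as follows: blocks
whose mean intensity falls below `fovFloor` are discarded as the black
camera surround (standard practice in fundus analysis — the aperture border
is uninformative and maximally uniform, so it would otherwise dominate any
uniformity ranking); among the remaining blocks the top `fraction` by GS are
kept, ties included — these are the most uniform blocks, which is where
lesion and disc interiors live; their pixels lying in the top `topBins`
occupied intensity bins are the candidate-lesion set, summarised by its mean
and Bessel-corrected standard deviation. The healthy reference pools the
same selection across all non-diseased training images. On a lesion-free
image the candidates are optic-disc pixels, so the distance is near zero; as
lesion burden grows, candidates mix ever more lesion area into the pool and
the distance rises. If fewer than two candidates exist the whole-image
distribution is used and flagged; note a *constant* image still yields
candidates (every block is uniform), returning its constant mean with the
clamped floor spread.

**Why the SVM kernels act on sorted feature vectors.** Lesions occur at
arbitrary retinal positions, so the per-block GS vector of an image is
exchangeable: two images with the same lesion burden typically depress
*different* coordinates. A position-wise kernel then sees two heavily
diseased images as farther apart than a healthy/diseased pair, and
one-vs-rest machines cannot form the band-shaped decision regions that
middle grades require. Both kernels therefore compare the *multiset* of
block values — the sorted vector — which makes similarity depend on lesion
burden, not lesion position. The default kernel is the Gaussian RBF
(bandwidth $1/(d\,\mathrm{var})$ unless set); the Hellinger affinity kernel
$\sum_i \sqrt{\hat x_i \hat y_i}$ on unit-sum-normalised vectors is provided
as a bounded, positive-semidefinite alternative that compares distribution
shapes. Being scale-invariant, the affinity kernel ignores overall feature
magnitude; where magnitude itself carries the signal the RBF kernel is the
right choice.

## The synthetic benchmark

`generateFundus()` renders, in order: a dark surround (intensity 8), a
circular retina field (radius 0.47 of the canvas, background 75), a vessel
tree walked out of the optic disc (intensity 30, jittered random walks), a
flat bright optic disc (intensity 215, radius 14–18 px, off-centre), and
`grade * 3` elliptical exudate-like lesions (semi-axes 6–12 px, per-lesion
intensity drawn from 180–240, placed inside the field and clear of the
disc), followed by additive Gaussian noise (sd 2) clipped to $[0,255]$.
Background, vessel and disc intensities are fixed across a dataset,
emulating capture with a single camera under uniform illumination, as in the
DIARETDB1-style protocols this generator imitates; per-lesion properties are
drawn per image. Identical specification and seed reproduce an image bit for
bit; datasets derive per-image seeds as `seed + index`, so any image can be
regenerated in isolation.

The standard benchmark used by the tests and by `scripts/acceptance.R` is 5
grades × 20 images at 256 × 256 — about a hundred images, sized so the whole
suite runs in well under a minute of feature extraction while leaving ~500
in-field blocks per image.

What the generator does **not** emulate: colour, uneven illumination and
vignetting, camera optics, haemorrhages and microaneurysms (dark lesions),
drusen-like confounders, and anatomical variation of the macula. Passing the
recovery tests therefore shows the pipeline's stages compose correctly and
respond to bright-lesion burden as designed — it does not certify clinical
performance on real photographs, which the source imagery of this kind
requires.

## Numerical choices and degenerate inputs

* Intensity bins are equal-width on $[0,256)$ with the final bin closed at
  255; a value at a bin edge goes to the higher bin. Bin indices are
  computed as $\lfloor v\,s_{\max}/256 \rfloor$, exact in doubles for 8-bit
  inputs.
* The vectorised extractor is verified bin-for-bin against a naive
  double-loop reference on images up to 32 × 32 (exact on counts, $10^{-9}$
  relative on normalised values).
* Ties at the GS quantile cut are included, so block selection never depends
  on storage order among equal values.
* Rank assignment uses strict inequality: a distance exactly at a threshold
  does not raise the grade.
* `assignRank`, `sensitivity` and `specificity` refuse undefined inputs
  (no diseased images, no healthy images) rather than returning NaN.
* One-vs-rest decision values are computed from stored support vectors and
  coefficients; kernlab solves the quadratic programs, after which the
  decision sign of each machine is oriented empirically on its training
  data. Prediction ties resolve to the lower grade.
* 16-bit images are rejected at load time; the histogram semantics are
  defined over the 8-bit range.

## Evaluation protocol

`runExperiment()` mirrors a dataset-size or window-size sweep: for each
value it takes a stratified 50/50 split by grade (seeded, deterministic),
fits the chosen ranker on one half and reports binary sensitivity and
specificity (diseased = predicted grade > 0), exact-match ranking efficiency
and the Spearman correlation between predicted and true grades on the other
half. Every metric is recomputed brute-force from the raw prediction lists
inside the harness as a wired-in cross-check. Feature-extraction wall time
is reported per image but is informational only: timing is
hardware-dependent and is never part of a correctness contract.

## Known limitations

* The severity distance saturates at high grade: once lesion pixels dominate
  the candidate pool, $(\mu, \sigma)$ stop moving, so per-grade mean
  distances rise steeply from grade 0 to 1 and flatten towards grade 4.
* Group sparsity is intensity-blind by construction; all intensity awareness
  enters through the bin layout (`sMax`) and the candidate-pixel bridge.
* The distance ranker's thresholds are dataset-dependent configuration; the
  defaults suit the synthetic benchmark's distance scale.
* The generator's lesions are bright ellipses only; methods tuned on it will
  not see dark-lesion pathology.
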