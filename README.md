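# FundusRank

Severity grading of diabetic retinopathy (DR) from retinal fundus
photographs, for researchers who need a transparent, fully testable
block-histogram pipeline rather than a black box. DR severity tracks the
burden of bright exudate lesions; FundusRank measures that burden with
sliding-window histogram features and ranks it on an ordinal 0–4 scale.

## Method

An 8-bit fundus image is tiled into non-overlapping `windowSize × windowSize`
blocks (edge blocks truncated). Each block's pixels are binned into `sMax`
equal-width intensity bins; the counts are normalised by the left- and
right-boundary constants `N/(sMax+1)` and `N/(sMax−1)` (`N` = block pixel
count) and summed, and the block is summarised by its group-sparsity value

    GS = Σ_k S_k²

over the combined histogram entries `S_k` — maximal for a uniform block,
depressed wherever a lesion boundary mixes intensities. Severity is scored
two ways:

* **Gaussian overlap distance.** Candidate-lesion pixels (top-intensity bins
  of the most uniform in-field blocks) give a distribution `(μ₁, σ₁)`
  compared against a healthy reference `(μ₂, σ₂)`:

      D = 1 − sqrt(2σ₁σ₂ / (σ₁² + σ₂²)) · exp(−¼ (μ₁ − μ₂)² / (σ₁² + σ₂²))

  `D ∈ [0, 1)` (one minus the Hellinger affinity of the two normals) is
  thresholded into grades.
* **Support-vector ranker.** A one-vs-rest soft-margin SVM (RBF or Hellinger
  affinity kernel over the sorted per-block GS vector) learns the grades
  directly.

Evaluation reports sensitivity `100·TP/(TP+FN)`, specificity
`100·TN/(TN+FP)` and ranking efficiency (percent exact grade agreement).
A seeded generator of DIARETDB1-style synthetic fundus images (retina field,
vessel tree, optic disc, exudate-like lesions scaling with grade) makes the
whole pipeline reproducible without external data.

## Worked example

```r
library(FundusRank)

ds  <- generateDataset(20, grades = 0:4, seed = 17)   # 100 images, 256x256
cfg <- WindowConfig()                                  # 8 px blocks, 2 bins

# per-grade mean severity distance to the healthy reference
fl  <- lapply(images(ds), extractFeatures, config = cfg)
rep <- severityReport(ds, cfg, featuresList = fl)
tapply(rep$distance, labels(ds)$severity_grade, mean)
#>            0            1            2            3            4
#> 0.0008995952 0.3138214989 0.4157586197 0.4545733572 0.4580216748

# SVM ranker on a stratified 50/50 held-out split
runExperiment(ds, cfg, sweep = "n_images", values = 100,
              ranker = "svm", seed = 1)
#>      sweep value n_train n_test sensitivity specificity ranking_efficiency
#> 1 n_images   100      50     50         100         100                 78
#>    spearman mean_extraction_ms
#> 1 0.9642274               1.49
```

The distance column shows healthy images scoring ≈ 0 and the score rising
with grade (saturating at high burden); the held-out SVM detects every
diseased image and recovers the exact grade for 78% of them, with Spearman
correlation 0.96 between predicted and true grades.

A command-line front end wrapping the same functions is installed at
`system.file("cli/fundusrank", package = "FundusRank")`:

```sh
fundusrank synth   --out imgs --grades 0,1,2,3,4 --n 20 --seed 17
fundusrank extract --in imgs --out features.csv
fundusrank rank    --in imgs --labels imgs/labels.csv --ranker svm --out ranks.csv
fundusrank eval    --in imgs --labels imgs/labels.csv --sweep window_size \
                   --values 4,8 --out report.csv
```

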