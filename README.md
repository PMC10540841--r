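# nutriface

Screening for **nutritional risk** from face photographs. Malnutrition
screening normally requires a structured bedside assessment (NRS-2002, a
validated 0–5 score where a score ≥ 3 flags nutritional risk). Because
disease-related malnutrition visibly depletes the orbital (sub-orbital) fat
pads, a face photograph carries a usable signal. `nutriface` implements the
full image-analysis chain that turns a photograph plus 68-point facial
landmarks into a binary risk call, and ships a synthetic-cohort generator so
the whole chain can be exercised, tested and benchmarked without any
clinical data.

The pipeline, stage by stage:

1. **Alignment** — eye centres are the centroids of landmark groups 36–41
   and 42–47; the image is rotated by −θ, θ = atan2(Δy, Δx) of the
   interocular line, about the eye midpoint so the eye line is horizontal.
2. **Cropping** — one similarity transform places the face centre on the
   vertical midline, the eye centre at 30% from the top and the mouth
   centre at 35% from the bottom of a 300 × 300 frame.
3. **Fat-pad segmentation** — a U-net (encoder–decoder with skip
   connections) trained with binary cross-entropy, batch size 1, RMSProp
   (lr 1e-5, weight decay 1e-8, momentum 0.9), 50 epochs; masks are 0/255
   rasters; quality is measured by Dice and per-class IoU.
4. **Texture features** — the masked ROI is described by dense HOG:
   8 × 8-px cells, 2 × 2-cell blocks at 1-cell stride, 9 unsigned
   orientation bins (centres i·π/9), L2-Hys normalization. A 300 × 300
   image yields 37 × 37 cells → 36 × 36 blocks → **46,656 features**.
5. **Standardize + PCA** — per-feature z-scores, then projection onto the
   top 100 principal components (both fitted on the training split only).
6. **Classification** — soft-margin SVM with RBF kernel
   K(x, y) = exp(−γ‖x−y‖²), C = 50, γ = 1e-5; positive class = NRS-2002 < 3.
   Performance is reported as accuracy, precision, recall and F1 from the
   TP/TN/FP/FN counts, plus subgroup tables (age group, gender, site) with
   Yates-corrected 2 × 2 chi-square tests.

## Worked example

```r
library(nutriface)

spec <- cohort_spec(300, effect_size = 2, seed = 1)   # 23.9% prevalence
cohort <- generate_cohort(spec)                       # in-memory cohort
cfg <- pipeline_config(use_true_masks = TRUE, pca_k = 100, seed = 1)
report <- run_pipeline(cohort, cfg)
report
```

```
nutriface run: 300 samples (222 train / 78 test), PCA k = 100
confusion: TP=63 TN=12 FP=2 FN=1
accuracy 96.2% | precision 96.9% | recall 98.4% | F1 97.7%
subgroup age_group (p = 1.000):
       level correct incorrect total  accuracy accuracy_pct p_value
     elderly       8         0     8 1.0000000        100.0       1
 non_elderly      67         3    70 0.9571429         95.7      NA
subgroup gender (p = 0.359):
  level correct incorrect total  accuracy accuracy_pct p_value
 female      33         0    33 1.0000000        100.0   0.359
   male      42         3    45 0.9333333         93.3      NA
subgroup site (p = 1.000):
      level correct incorrect total  accuracy accuracy_pct p_value
 non_remote      52         2    54 0.9629630         96.3       1
     remote      23         1    24 0.9583333         95.8      NA
```

Here the generator planted a 2-standard-deviation appearance difference
between risk classes, and the HOG → PCA → SVM chain recovers it: 96.2% of
the 78 held-out subjects are classified correctly (63 true positives, i.e.
correctly recognised low-risk subjects; 12 correctly flagged risk
subjects). The subgroup tables report per-level accuracy and a
Yates-corrected chi-square p-value for homogeneity, mirroring the layout of
a clinical evaluation; as in a cohort where demographics are independent of
the label, none of the subgroup differences is significant.

To train the segmentation stage instead of using ground-truth masks, drop
`use_true_masks` and pass a `seg_train_config()`; desk-scale settings
(128 × 128 inputs, depth 2, 16 base channels, lr 5e-4, RMS smoothing 0.9)
train in minutes on one CPU.

A command-line front end over the same functions is installed at
`system.file("cli", "nutriface.R", package = "nutriface")` with verbs
`synth`, `align`, `train-seg`, `segment`, `extract-features`, `train-clf`,
`evaluate`, `subgroups`, `run-all`.

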