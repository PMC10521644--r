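---
title: "Low-cost augmentation search: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-cost augmentation search: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deep classifiers for dermoscopic skin-lesion images face two chronic
obstacles: datasets are small and severely class-imbalanced (a typical
7-class archive spans two orders of magnitude between the largest and the
smallest class), and automatic augmentation-policy searches that help on
natural images are far too expensive to re-run per clinical dataset (search
spaces of 10^32 candidates and beyond). `lcaugment` implements a deliberately
small augmentation search space — 12 subpolicies, each a (color op,
geometric op) pair, governed by a single execution probability drawn from
the 5-step ladder {0.1, 0.3, 0.5, 0.7, 0.9} — so the whole space has
12 × 5 = 60 combinations and the only searched hyperparameter is the
probability.

## The augmentation model

Each training image draws one subpolicy uniformly from the space. The two
ops of the chosen subpolicy then execute *independently*, each with the
strategy probability P; an executing op draws its magnitude uniformly from
its configured range. The color op is applied before the geometric op.

Three of these conventions are genuinely open in the procedure as published,
and are fixed here as package design choices:

* **Execution semantics.** "The execution probability of the two operations
  is the same" is read as independent per-op Bernoulli(P) executions. The
  alternative reading (the subpolicy fires as a unit) is expressible by
  pairing ops into a single custom op, but independent execution is the
  default because it keeps color and geometric ops exactly equally likely
  while preserving a single hyperparameter.
* **Order.** Color before geometric — arbitrary but fixed, so that seeded
  runs are reproducible. For the ops shipped the two orders differ only
  through interpolation and clipping details.
* **Magnitude law.** Uniform on the op's closed range, resampled per image
  and per execution.

The concrete roster of 12 color ops (brightness, contrast, saturation, hue
shift, white-balance jitter, Gaussian noise, sharpness, posterize, solarize,
equalize, autocontrast, gamma) and 6 geometric ops (horizontal flip,
vertical flip, rotate ±30°, scale 0.8–1.2, translate ±0.2, shear ±0.3),
their pairings (each geometric op appears in exactly two subpolicies), and
the magnitude ranges follow the families named for the method plus ranges
conventional in the auto-augmentation literature. They are defaults, not
constants: `space_from_yaml()` loads any other roster with custom ranges.

Geometric warps keep the output frame equal to the input frame and fill
exposed pixels by edge reflection (bilinear resampling); `scale` is a
center zoom with the same reflective fill, so downstream crop geometry is
always valid. Every op clips to the valid intensity range. With P = 0 the
executor returns the input untouched *without consuming the random stream*,
making a zero-probability strategy bit-identical to no augmentation — a
property the trainer tests rely on.

## Loss, metrics, evaluation

Class imbalance is handled by inverse-frequency weights `w_i = N / n_i`
multiplying the standard softmax cross-entropy per class. Weights are kept
unnormalised (balanced data gives `w_i = C` for all classes, a pure loss
rescaling that Adam absorbs), and are always computed from the training
split of a fold, never its validation split. The log is clamped at 1e-12.

The headline metric is balanced multiclass accuracy (BACC), the unweighted
mean of per-class sensitivities; per-class precision, specificity and
accuracy, and a macro one-vs-rest AUC (normalised Mann–Whitney U, ties at
half credit) complete the report. Ratios with zero denominators — possible
on small synthetic folds that lack a class — are reported as missing and
excluded from macro averages with a warning rather than silently zeroed.

Test-time evaluation averages class probabilities over a fixed grid of
crops: top-left offsets are the rounded linear spacing from 0 to the
maximal offset along each axis, inclusive of both extremes. With the
defaults (224 × 224 crops, 4 per axis) a 600 × 450 image yields 16 regions
of interest from the upper-left to the lower-right corner. Probabilities
(not logits) are averaged, so the result is again a probability vector.

## The two-stage search

Stage 1 selects the probability by grouped 5-fold cross-validation: groups
(lesions) are assigned to folds by a seeded greedy shuffle that balances
fold sizes at roughly 4:1 train:validation while never splitting a lesion
across the two sides. For every candidate probability and backbone, each
fold is trained and the per-fold score is the *best* validation BACC over
epoch checkpoints; the screening criterion is the mean of the five per-fold
scores. Across backbones the selected probability is the majority vote of
per-backbone argmaxes, ties broken by the higher mean criterion (this
mirrors the published selection logic, where the winning probability was
the one preferred by most of the candidate networks). Training seeds are
shared across candidate probabilities, so candidates are compared on
identical folds and identical initialisations.

Stage 2 retrains each backbone on the full training set with the winning
strategy and evaluates multi-crop test BACC every `checkpoint_every`
epochs; the backbone with the best test BACC is recommended. The whole run
serialises to a JSON `SearchReport`, and a fixed seed reproduces the report
byte for byte.

The training protocol mirrors the reference schedule: Adam, initial
learning rate 1e-3, divided by 10 after 20 epochs and again every 10
epochs, 70 epochs, batch size 32, random 224 × 224 crops of augmented
images. All of these are `train_config()` fields; the desk-scale defaults
used by the tests and the acceptance script are noted below.

## Grad-CAM++

Visual explanations follow the three-equation pipeline: pixel-wise weights
`alpha = d2 / (2 d2 + sum_mn(A d3))` per feature map, channel weights
`w_k = sum_mn alpha · relu(d1)`, and heatmap `L = relu(sum_k w_k A_k)`,
where `d1..d3` are the first three derivatives of the target class score
with respect to the last-convolution feature maps. Two numerical
conventions: where the alpha denominator is smaller than 1e-8 in magnitude
it is replaced by 1 (a linear head then degrades gracefully to a zero map
instead of NaN), and a constant heatmap min–max-normalises to all zeros.
The derivative source is the backbone's concern: the reference CNN supplies
them analytically through the exponentiated-score form, under which even a
linear head has non-vanishing second and third derivatives; the test suite
cross-checks the analytic path against central finite differences on a
fixed polynomial-head model.

## The reference backbone

`tiny_cnn_backbone()` is two strided valid 3 × 3 convolutions with ReLU
(12 filters each by default) and a dense softmax head on the flattened
feature maps — under a thousand to a few thousand parameters, trainable on
one CPU in seconds. The flatten head is the default deliberately: it gives
the network enough capacity to overfit a few hundred images, which is the
regime in which an augmentation policy has something to regularise; a
`"gap"` (global-average-pooling) head is available as an even smaller
variant. The backbone is pluggable: anything implementing
`init`/`forward`/`backward` (and optionally `gradcam`) through the
`lca_backbone` contract can be searched.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` renders skin-tone backgrounds with a gentle
illumination field and a centred elliptical lesion whose HSV color,
eccentricity, size and radial border irregularity are class-conditional;
images of one lesion group share base parameters and photographic framing
up to small jitter, emulating repeated dermoscopy of the same lesion. The
default spec mirrors a 7-class archive's imbalance scaled to 700 images
(counts 468 down to 8), so weighted-loss effects are visible at desk scale.
It does *not* emulate hair, rulers, gel bubbles, vignetting, camera noise
statistics, or the intra-class texture diversity of real dermoscopy —
passing tests on this generator demonstrate correctness and sensible
behaviour of the search machinery, not clinical performance.

`planted_invariance_dataset()` supports parameter-recovery experiments.
In the `color-nuisance` variant the class is carried purely by lesion
geometry (eccentricity and border irregularity; lesion size is held
class-constant so the scale op cannot corrupt labels), while hue,
saturation and brightness are drawn per lesion group — color is a
memorisable shortcut that generalises to no other lesion. In
`shape-nuisance` the roles are reversed. The default profile is
class-imbalanced (180/100/70/50) with four images per lesion sharing one
photographic framing: few distinct lesions per class and a strong
per-lesion color shortcut are exactly the conditions under which an
augmentation policy should pay off, and the acceptance experiment checks
that the stage-1 search prefers a nonzero execution probability there.

## Desk-scale study conditions

The end-to-end experiments in the tests and the acceptance script use:
400-image 4-class planted datasets at 64 × 64, the reference CNN (12 + 12
filters, flatten head), grouped 5-fold cross-validation, 10 epochs per
fold, batch size 8, random 56 × 56 crops, and Adam at 3e-3. The small
batch and raised learning rate give the optimiser enough steps to fit the
geometric signal inside a 10-epoch fold budget — the 70-epoch 1e-3
protocol is meant for full-scale runs and barely moves a model in 10
epochs at this image size. The reduced probability ladder for recovery
runs includes the no-augmentation candidate P = 0 alongside the low
probabilities 0.1 and 0.3, because low P is where short-budget training
benefits from augmentation — consistent with the published observation
that the searched optimum lay at 0.1–0.3.

## Known limitations

* The op roster and magnitude ranges are reconstructions of the published
  transform families, not a verbatim table; use the YAML schema to match a
  specific table exactly.
* The reference CNN is a correctness and search vehicle, not a competitive
  dermoscopy classifier; no pretrained weights are shipped.
* Multi-crop evaluation assumes the unscaled image is at least the crop
  size in both dimensions; images are never rescaled before cropping.
* Grad-CAM++ heatmap normalisation and bilinear upsampling for overlays
  are display conventions; the raw map `L` is the quantity defined by the
  equations.
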