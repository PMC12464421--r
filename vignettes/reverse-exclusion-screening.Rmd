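---
title: "Benign-first reverse-exclusion screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benign-first reverse-exclusion screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nevuscreen)
```

## The screening model

Early melanomas mimic benign melanocytic nevi closely enough that training a
detector to find *melanoma* directly runs into scarce, heterogeneous positive
examples. The reverse-exclusion strategy inverts the task: a detector is
trained only on benign nevi — lesions that are symmetric, uniformly
pigmented, and sharply demarcated. At screening time, an image in which the
detector confidently finds a nevus is labelled **low-risk**; an image with no
confident nevus detection is labelled **high-risk** and referred for biopsy.
Because a growing melanoma disrupts at least one of the three benign
criteria, the safety-critical error collapses to a single number: the
false-negative rate

$$\mathrm{FNR} = \frac{FN}{TP + FN},$$

where $FN$ counts melanomas called nevus and $TP$ counts melanomas correctly
flagged non-nevus. (Clinical summaries sometimes label the correctly
excluded cases "TN"; the formula above requires the $TP$ convention, and
`print.screening_counts()` shows both labels.) The clinical ceiling used
throughout is $\mathrm{FNR} \le 0.5\%$, with an *inclusive* comparison, and
the detection-confidence threshold of 0.5 is likewise inclusive, so a
detection at exactly 0.5 counts as a nevus call. Reader comparisons use the
exact McNemar test — a two-sided exact binomial test on discordant pairs —
via `mcnemar_exact()`, which delegates the tail computation to
`stats::binom.test()`.

## The Shape-IoU box loss

Bounding-box regression uses a shape-aware extension of IoU. For a
prediction $B = (x_c, y_c, w, h)$ and ground truth $B^{gt}$ (centre form,
units-agnostic), with a dataset-level size factor $s \ge 0$:

$$ww = \frac{2\,(w^{gt})^{s}}{(w^{gt})^{s} + (h^{gt})^{s}}, \qquad
hh = \frac{2\,(h^{gt})^{s}}{(w^{gt})^{s} + (h^{gt})^{s}},$$

$$\mathrm{distance}^{shape} = hh\,\frac{(x_c - x_c^{gt})^2}{c^2}
 + ww\,\frac{(y_c - y_c^{gt})^2}{c^2},$$

$$\Omega^{shape} = \sum_{t \in \{w, h\}} (1 - e^{-\omega_t})^{\theta},
\quad \theta = 4, \qquad
\omega_w = hh\,\frac{|w - w^{gt}|}{\max(w, w^{gt})},\;
\omega_h = ww\,\frac{|h - h^{gt}|}{\max(h, h^{gt})},$$

$$L = 1 - \mathrm{IoU} + \mathrm{distance}^{shape} + 0.5\,\Omega^{shape}.$$

Three implementation decisions deserve emphasis:

* **Cross-weighting is kept exactly as defined** — the *height* weight $hh$
  multiplies the x/width terms and $ww$ the y/height terms, even though it
  can look transposed. The defining formulas are unambiguous on this point
  and the implementation follows them verbatim.
* **`scale` defaults to 0**, which collapses $ww = hh = 1$. The factor is
  described only as a dataset-level constant reflecting typical target
  size; with no rule given for deriving it, the only forced choice is the
  neutral one, exposed as a configuration hook (`shape_iou_params()`,
  `detector_config(shape_scale = )`). It is treated as global, not
  per-image.
* **$c^2$ is the squared diagonal of the minimum enclosing axis-aligned
  rectangle** of the two boxes. All boxes here are axis-aligned, so the
  axis-aligned reading of the enclosing ("convex hull") box is the natural
  one.

Degenerate inputs are guarded by a $10^{-9}$ floor on $\max(w, w^{gt})$,
$c^2$ and the union area. `shape_iou_grad()` provides the analytic gradient
used both by the finite-difference test suite and by the training engine;
at the measure-zero ties (equal widths, aligned corners) it returns a
subgradient. A CIoU baseline (`ciou_loss()`, with the customary
constant-$\alpha$ gradient convention) supports the ablation configuration.

One property worth stating precisely: compared with a plain $1 -
\mathrm{IoU}$ objective at the same learning rate, the normalised centre
penalty makes the *centre offset* decay at least as fast, and it keeps a
useful gradient when the boxes are disjoint (plain IoU is flat there). The
raw number of steps to reach IoU $\ge 0.99$ is, however, not uniformly
smaller: the enclosing-box normalisation couples $c^2$ to $w, h$ and can
transiently inflate the prediction. The regression tests assert the
properties that actually hold.

## Multidimensional collaborative attention

The MCA block models attention independently along the channel, width and
height axes of a $C \times H \times W$ map. Each branch:

1. **squeezes** the map to a descriptor by a *learned convex fusion* of
   average pooling and standard-deviation pooling (luminance and texture
   dispersion). Max pooling is computed as a third context statistic and
   can be added to the fusion behind `use_max_pool`, but is excluded by
   default: the fusion is specified for the avg/std pair only.
2. **excites** the descriptor with a 1-D local convolution of odd width
   $k$ followed by a sigmoid, in place of an MLP reduction. When
   `kernel_size = "adaptive"`, $k$ is the nearest odd integer to
   $\log_2(\mathrm{len})/2 + 1/2$, floored at 3 — the standard heuristic
   for channel-descriptor excitation. The "grouped" convolution is realised
   as a single shared kernel per branch; branch weights are not shared.

The three sigmoid-normalised attention maps are broadcast to the input
shape and **averaged**, which keeps every attention value strictly inside
$(0, 1)$ and damps single-branch noise; the input is then scaled
elementwise. Fusion weights are parameterised through a softmax pair inside
the detector so convexity is structural. Excitation kernels initialise to
zero, i.e. every attention weight starts at the neutral 0.5.

## Detector assembly

The detector keeps a conventional three-stage, single-class layout:

* **Backbone** (texture fidelity): a stem convolution followed by seven
  depthwise-separable stages with H-Swish activations, 5×5 kernels and
  squeeze-and-excitation in the tail stages, holding the first stages at
  1/4 and 1/8 resolution before tapping P3 (1/8), P4 (1/16) and P5 (1/32).
  At 1/32 an SPPF block (three serial 5×5 max-pools, concatenated) expands
  the receptive field and an SE-style global recalibration stands in for
  the PSA block, which has no single standard definition. A plain-convolution
  baseline backbone with identical tap widths backs the ablation toggle. A
  classification-pretrain projection (global pool + 1×1) is built but
  unused: detection trains from random initialisation.
* **Neck** (multiscale aggregation): top-down path-aggregation — upsample
  P5, concatenate with P4, fuse with a split-merge (C2f-style) block to
  P4′, likewise to P3′ — then bottom-up via separable stride-2 (SCDown)
  reductions to P4″ and P5″. An MCA block sits before each of the three
  output nodes (identity when the toggle is off). C2f and SCDown follow
  their common definitions (split/bottleneck/merge; depthwise stride-2 +
  pointwise), since only their names are prescribed.
* **Head** (shape-sensitive regression): decoupled classification and
  regression branches per scale, duplicated for the **one-to-many** and
  **one-to-one** assignment branches. Regression uses distribution focal
  loss with 16 bins per side, decoded by softmax expectation into
  left/top/right/bottom distances in stride units. Training runs both
  assignment branches in parallel (task-aligned metric
  $\mathrm{score}^{\alpha}\,\mathrm{IoU}^{\beta}$ with $\alpha = 1$,
  $\beta = 6$, top-$k = 10$ for one-to-many, top-1 for one-to-one,
  candidate anchors restricted to centres inside the ground-truth box,
  ties broken to the lowest anchor index). Inference keeps only the
  one-to-one branch and applies **no NMS**.

No deep-learning framework is involved: the package carries a small
tape-based reverse-mode differentiation engine with compiled convolution
and pooling kernels, supporting exactly the operations above. Gradients of
the box loss reach the regression logits through the analytic Shape-IoU
gradient chained through the DFL decode.

### Training profiles and problem sizes

The full-resolution profile freezes the reference clinical-scale schedule
(`detector_train_defaults()`): 640 px input, batch 64, 100 epochs, SGD with
momentum 0.9 and weight decay $5\times10^{-4}$, cosine learning rate
$0.01 \to 10^{-5}$, validation mAP@0.5 every 5 epochs, early stop after 15
stagnant epochs, best-validation checkpoint restored.

The default **tiny profile** is the package's own choice for CPU desk-scale
work: 64 px input, channel widths (8, 16, 32, 64, 96), batch 16, 30 epochs,
~450k parameters, the same optimiser and schedule. The end-to-end rehearsal
exercised by the test suite and the acceptance script trains this profile
on 200 synthetic benign images, validates on the ~40 held-out benign
images, and screens 100 synthetic melanomas; the whole rehearsal runs in a
few minutes on one CPU. Images are normalised to $[0,1]$ and standardised
channel-wise with the ImageNet constants (0.485, 0.456, 0.406) /
(0.229, 0.224, 0.225).

## Detection metrics

Matching is greedy in descending score order; a detection is a true
positive only when its IoU with a still-unmatched ground truth reaches the
threshold (0.5 for the headline metric), each ground truth matching at most
once. Precision and recall are reported at confidence 0.5, while average
precision sweeps all confidences and integrates the precision–recall curve
with all-point interpolation (the precision envelope), matching the
convention of the detector ecosystem these numbers are usually compared
against. The range metric averages AP over IoU 0.50–0.95 in steps of 0.05
and can never exceed mAP@0.5; because this quantity is sometimes labelled
"mAP@0.95" in results tables, the evaluation report exposes `map95` as an
alias of `map50_95`.

## Morphometrics

The morphology suite quantifies the boundary behaviour that separates
malignant from benign outlines:

* **Skeleton topology** — Zhang–Suen two-subcycle thinning to a 1-px,
  connectivity-preserving skeleton. Terminals are skeleton pixels with
  exactly one neighbour. Branch points use the *crossing number* (≥ 3
  0→1 transitions around the 8-neighbour cycle) rather than a raw ≥ 3
  neighbour count: at a simple crossing the raw count flags a 5-pixel
  cluster, while the crossing number counts one branch point, which is
  the topologically meaningful census.
* **Scale-resolved fractal dimension** — windows of side $s \in \{16, 32,
  64, 128, 256\}$ px slide along the boundary; within each window the
  boundary pixels are box-counted at the dyadic sizes $s/16, s/8, s/4$
  (floored at 2 px) and the local dimension is the regression slope of
  $\log N$ on $\log(1/\varepsilon)$, clipped to $[1, 2]$. The range is a
  package choice: below $s/16$ the raster pixel floor flattens the count,
  above $s/4$ the window saturates. A depth-4 Koch boundary measured with
  a 128 px window recovers $\approx 1.24$ against the theoretical
  $\log 4 / \log 3 \approx 1.262$.
* **Elliptic Fourier descriptors** — Kuhl–Giardina coefficients under
  arc-length parameterisation, reported as per-harmonic magnitudes
  $\sqrt{a^2+b^2+c^2+d^2}$ normalised by harmonic 1 (so the spectrum is
  dimensionless). Two mathematical facts shape the tests: an eccentric
  ellipse parameterised by arc length is *not* exactly single-harmonic
  (small odd harmonics appear, ~0.09 at 2.5:1 eccentricity), and an
  $m$-fold symmetric outline concentrates its lobe energy at harmonics
  $m \pm 1$, not $m$. The suite asserts first-harmonic dominance and the
  side-band structure accordingly.
* **Radial-distance profile** — radius from the mask-moment centroid per
  angular bin (360 bins), using a star-shaped maximum reduction when a ray
  crosses the boundary more than once (the fraction of multi-crossing bins
  is reported); empty bins are filled by circular interpolation. Summaries:
  mean radius, oscillation $(\max - \min)/\bar r$, and `frac_over(t)`, the
  fraction of *contour points* whose normalised deviation exceeds $t$
  (contour points, not angular bins, is the implemented reading). The
  outline $r = 1 + 0.16\cos 2\varphi$ oscillates by exactly 32% of its
  mean radius, and a benign/malignant screening rule of
  `frac_over(0.10) <= 0.15` separates the generator's classes.

`benign_criteria_report()` bundles these with two pigment criteria measured
on the RGB image: within-lesion colour dispersion (mean per-channel SD;
benign outlines stay below 0.10 by construction) and border sharpness (mean
normalised intensity step across a ±2 px span normal to the boundary).

## The synthetic generator

`make_cohort()`, `gen_mask()`, `render_lesion()` and `augment_sample()`
emulate the screening-study conditions end to end:

* **Cohort composition** is allocated deterministically (largest
  remainder) from the reference full-scale counts: phototypes II/III
  1,115/1,290 of 2,405 (46.36%/53.64%) and hair-occlusion grades
  2,258/104/43 (6.11% occluded overall), at any requested scale; benign
  images form the training pool (2,040 at full scale) and melanomas
  (365) an external screening set never used in training.
* **Outlines** are radial harmonic curves
  $r(\varphi) = R\,(1 + \sum_k a_k \cos(k\varphi + \phi_k))$. Benign specs
  budget the total modulation below 4% of the radius — oscillation safely
  under 10% and `frac_over(0.10) = 0`. Malignant specs always violate the
  shape criterion (lobes $a_{2..5} \in [0.12, 0.22]$ and/or serration at
  harmonics 9–15), and with probability 0.5 each additionally violate
  pigment homogeneity (3–6 Gaussian patches, contrast 0.15–0.30) or border
  sharpness (blend width 6–12 px versus ≤ 2 px benign). The amplitude
  budgets are anchored to the literature-style thresholds (colour variance
  < 0.10, sharp borders) rather than invented per test.
* **Rendering** composites the pigment over a procedural skin background
  (low-frequency tone field + speckle; phototype II lighter than III) with
  the border blended over the softness width, and draws quadratic-Bézier
  hair strokes at grades 1 (sparse, lighter) and 2 (dense, dark).
* **Augmentation** applies horizontal/vertical flips ($p = 0.5 / 0.3$),
  random scaling 0.5–1.2×, HSV jitter (H ±20%, S ±30%, V ±30%), Gaussian
  noise $\sigma = 0.1$, and rectangular occlusion (area ≤ 20%, aspect
  0.5–2). No application rate is prescribed for the occlusion operator;
  the package applies it with probability 0.3. Geometric operators
  transform the ground-truth box analytically; the suite checks the
  recomputed mask bbox stays within 1 px.

What the generator does **not** emulate: dermoscope optics, real pigment
network texture, hair removal artefacts, or the intra-class ambiguity of
real early melanomas. Passing the rehearsal therefore shows the pipeline is
correctly wired and trainable — it does not certify clinical performance.
In particular, the tiny detector generalises its "dark blob" notion far
more readily than a clinical-scale system trained on real dermoscopy, so
the synthetic screening FNR it reports is a pipeline readout, not a
clinical miss rate; the acceptance rehearsal asserts the formula-path
identity of the FNR computation and the benign-detection mAP, never a
synthetic FNR value.

## Numerical choices and degenerate inputs

* Thresholds that gate clinical decisions (confidence 0.5, FNR ceiling
  0.5%) compare inclusively.
* Division floors of $10^{-9}$ guard IoU unions, $c^2$ and the
  width/height maxima; DFL targets clip to $[0, 15 - 10^{-3}]$ bins.
* Batch normalisation uses batch statistics in training and running
  averages (momentum 0.1) at inference; the std-pooling backward adds
  $10^{-10}$ inside the square root.
* Ties in label assignment resolve to the lowest anchor index; anchors
  claimed by two ground truths go to the higher-IoU one; a ground truth
  containing no anchor centre falls back to the highest-IoU anchor.
* Empty masks, open contours, sub-3-point contours and empty cohorts raise
  errors rather than returning silent defaults.

## Known limitations

The training engine is deliberately minimal (no EMA, no mosaic/mixup, no
mixed precision, single-class head); the tiny profile's DFL bins are coarse
at stride 32; and the morphology suite assumes a single dominant lesion per
mask (the largest connected component). The 640 px profile is provided but
is not practical to train on one CPU; its defaults are frozen so the
configuration is faithful where the computation is not affordable.
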