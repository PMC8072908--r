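---
title: "Breast-mass detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breast-mass detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mammocad detects breast masses in grayscale mammograms with a four-stage
pipeline that mirrors how a reader scans a film: highlight everything that
could be a mass, locate the highlighted regions, decide which of them
really are masses, and then tighten the box around each accepted one.
This vignette explains each stage's model and assumptions, the parameters
that matter, the synthetic phantoms used for testing, and the places where
the design was genuinely open.

## 1. Morphological highlighting

Masses are denser than surrounding tissue and therefore locally brighter,
but their edges are blurred and their texture is complex.  The first stage
applies grayscale erosion with a small elliptical structuring element
(default 7x7 pixels) followed by dilation with a large one (default
50x50):

* erosion is a sliding minimum — isolated bright speckle smaller than the
  element vanishes;
* dilation is a sliding maximum — each surviving bright region is inflated
  into a near-circular plateau of roughly the dilating element's
  footprint, which is the shape the matching template expects.

This is deliberately *not* a morphological opening: the two elements
differ, and the implementation makes no attempt to "correct" that.  Two
choices the operators leave open:

* **Border policy.** Out-of-bounds neighbours replicate the nearest edge
  pixel, so constant images are fixed points and borders are not darkened
  by erosion or brightened by dilation.
* **Ellipse membership.** A cell at offset $(r, c)$ from the anchor is in
  the element iff $(c/a)^2 + (r/b)^2 \le 1$ with $a = (w-1)/2$,
  $b = (h-1)/2$.  This reproduces the common library definition and
  guarantees the anchor cell is active.

Images are processed at native bit depth (8-bit by default); no intensity
normalization precedes morphology.

## 2. Template matching

A parametric circular-mass template (default 68x60 pixels) ramps linearly
in radius from 117 at the centre to 104 on the inscribed-ellipse boundary,
with 104 outside — the intensity regime of a typical mass after the
morphology stage.  Matching slides the template over the preprocessed
image and computes the squared-difference distance

$$D(i,j) = \sum_{m=1}^{M}\sum_{n=1}^{N} \left[P(m,n) - T(m,n)\right]^2,$$

evaluated exactly as written (no square root).  Because a threshold in
$[0,1]$ is applied to a *matching degree* rather than to $D$ itself, the
degree is defined as the normalized squared-difference similarity

$$\mathrm{degree}(i,j) = 1 - \frac{D(i,j)}{\sqrt{\sum P^2 \cdot \sum T^2}},$$

clipped to $[0,1]$: it is 1 exactly at a perfect match, 0.5 for a patch
that is twice the template, and bounded for any intensity scale.  Both
all-zero operands define degree 1 (identical); exactly one all-zero
operand defines degree 0.  The raw distance map remains available
separately.

Candidates are local maxima of the degree map at or above the matching
threshold (default 0.7).  A cell is a peak when it is $\ge$ all eight
neighbours; plateaus of equal-valued connected peak cells contribute their
centroid.  Two practical points discovered on synthetic data:

* **Degree-map smoothing** (`degree_smooth_sigma`, default 8 px, pipeline
  only).  After dilation a mass becomes a plateau much larger than the
  template, so the degree map is near-constant over tens of pixels and
  pixel noise splinters it into several off-centre peaks per mass.
  Smoothing at roughly the noise correlation scale consolidates each
  plateau into a single centred peak; on the default phantoms this raised
  the median rough-box IoU against ground truth from about 0.61 to 0.71.
  Smoothing is applied to the map only; the peak rule is unchanged.
* Matching runs on the *preprocessed* image, but candidate patches are
  cropped from the *original* (resized) image — the classifier should see
  real tissue, not plateaus.

Overlapping candidates merge while any pair's IoU exceeds 0.3, always the
highest-IoU pair first (deterministic tie-break), the merged box being the
smallest box containing both and the merged degree the pair's maximum.
Merging to a fixpoint guarantees all pairwise IoUs end at or below the
threshold and makes the operation idempotent.

## 3. The patch classifier

Candidates are resized to 200x200 and classified mass vs background by a
small CNN: three blocks of convolution (stride 1, zero "same" padding) →
batch normalization → ReLU → 2x2/2 max-pool, with 128 kernels per block of
sizes 5x5, 3x3, 3x3; then a 1024-node fully connected layer (ReLU) and a
2-way softmax.  Three poolings turn the 200x200 input into 25x25x128
feature maps, so the model has 82,222,338 parameters, dominated by the
first fully connected layer.  Patch intensities are scaled to $[0,1]$;
the loss is cross-entropy under plain SGD; training stops at the epoch cap
or as soon as the full-training-set accuracy (recomputed each epoch in
evaluation mode) reaches 100%.

Where the architecture description is ambiguous, the conventional reading
was chosen: conv → BN → ReLU → pool inside each block, and ReLU after the
first fully connected layer.  No data augmentation is applied.

Since no deep-learning framework is available to R, the network is
implemented in the package's own C++ (RcppArmadillo): convolutions are
im2col plus one single-precision GEMM per layer over the whole minibatch,
with full backpropagation through pooling, batch norm and the ReLUs.
Training is bit-reproducible given the configuration seed (weights,
shuffling and batch statistics are all derived from it).

**Default vs desk-scale training.**  The package defaults keep the
published recipe (learning rate $10^{-4}$, up to 200 epochs), which
targets a corpus of thousands of clinical patches.  The test suite and the
acceptance script train on a few hundred synthetic patches and use a
desk-scale recipe chosen once during development: learning rate
$3\times10^{-3}$, batch size 16, batch-norm momentum 0.3, epoch cap 50.
On the default phantom patches this reaches 100% training accuracy within
one or two epochs and generalizes essentially perfectly, because the
synthetic classes are well separated.

## 4. PSO box refinement

The boxes produced by matching are rough: the template has one fixed size
and the morphology stage normalizes every bright region to the dilating
element's footprint.  Each accepted box is therefore refined by particle
swarm optimization over a search region made of the rough box expanded by
30% of its width left and right and 30% of its height up and down.  A
particle's position is the box in centre form $(x, y, w, h)$; velocities
update as

$$V_i \leftarrow V_i + c_p\,\mathrm{rand}() \,(pbest_i - X_i) + c_g\,\mathrm{rand}()\,(gbest - X_i), \qquad X_i \leftarrow X_i + V_i,$$

with $c_p = c_g = 0.5$, independent uniform random weights per coordinate,
and the classifier's mass probability of the decoded, cropped, resized box
as fitness.  Personal and global bests store *positions* and *fitnesses*
separately (the printed algorithm conflates them in a way that cannot
execute), and both update only on strict improvement, so the global best
trace is non-decreasing and — because particle 1 starts at the rough box —
the returned fitness never falls below the rough box's.

Choices the equations leave open, and how they were made:

* **Initialization.**  Initializing every particle at the rough box with
  zero velocity (as printed) provably never moves.  Particle 1 keeps the
  rough box; the others jitter locally around it (centre within ±30% of
  the box size, scale in about $[0.7, 1.4]\times$), with small random
  initial velocities.  A uniform spread over the whole search region was
  tried first and rejected: it starts the search from arbitrarily tiny
  boxes, and because a tight crop of a mass centre scores high under the
  classifier, the swarm then collapses boxes and *worsens* IoU.
* **No inertia weight** (none in the update rule); velocities are instead
  clamped to ±50% of the search-region size per coordinate.
* **Decoding** clamps width/height to [8 px, region size] and shifts the
  centre so the box stays inside the region.
* **Duplicate suppression.**  Refinement draws duplicated candidates of
  one mass onto the same region; among accepted detections whose final
  boxes overlap above the merge IoU only the highest-probability one is
  emitted (`final_nms`).  Classification-level metrics still count the
  pre-suppression decisions.

A known limitation, visible on the phantoms: when the classifier's
probabilities saturate, the fitness surface over the search region is
nearly flat with a mild gradient toward bright, tight crops, so individual
refinements can shrink a box past the mass boundary.  The local
initialization, the strict-improvement tie-keeping and the suppression
step bound the damage (median refined IoU exceeds median rough IoU on the
test phantoms), but refinement quality is ultimately limited by how
informative the classifier's probability is about localization.

## 5. Synthetic phantoms

`generate_phantom()` builds mammogram-like test images with known ground
truth: a dark background (level 60 on the 8-bit scale), smooth
low-frequency texture (white noise smoothed at a 40 px correlation scale,
rescaled to sd 8; the noise field is generated on a padded canvas so
border replication cannot inflate the local variance), planted masses as
filled ellipses with semi-axes 24–34 px and peak intensity 45–75 above
background, softened by a 3 px Gaussian blur, and additive pixel noise
(sd 3).  Ground-truth boxes are the tight boxes of the unblurred ellipses;
planted boxes are disjoint and fully inside the image.  Default phantoms
are 400x400 px with two masses, and detection runs at native size
(`resize_to = NULL`): the published 1500x2000 working size refers to
full-field clinical images, and at desk scale the phantom masses are
already in the template's size regime.

The mass semi-axis range was chosen so ground-truth boxes (48–68 px)
bracket the 68x60 template: a centred template-sized box then overlaps any
planted mass at IoU ≥ 0.5, which is what makes the fixed-size rough boxes
a usable starting point, exactly as the fixed template presumes masses of
roughly its scale.  Mass peak intensity stays well above the texture
amplitude so the brightest structure in a noise-free phantom is always a
mass.

What the phantoms deliberately do **not** model: pectoral muscle, labels
and artifacts, spiculated or non-elliptical lesions, calcification
clusters, tissue overlap, and scanner characteristics.  Passing tests on
phantoms therefore demonstrate that the pipeline's machinery works as
specified — they are not evidence of clinical performance on real
mammograms.

`generate_patch_dataset()` mirrors the way training patches are built in
practice: mass patches are jittered crops of the ground-truth boxes (up to
two per planted mass; positional jitter ≤ 10% of the box size), background
patches are mass-sized crops whose IoU with every ground-truth box is
exactly 0.  Everything is reproducible from the spec seed.

## 6. Evaluation

Detection metrics follow standard practice because the hit criterion is
otherwise undefined: a detection is a true positive iff it can be greedily
matched (in order of descending probability) to an unclaimed ground-truth
box at IoU ≥ 0.5 (`tp_iou_threshold`, configurable).  TPR is matched
truths over all truths; FPI is unmatched detections per image.  Accuracy,
precision, recall and F1 are computed at the *candidate classification*
level — over all scored candidates, a candidate being truly positive when
its rough box reaches the TP IoU against any truth — which is why they can
differ from the detection-level TPR.  On instances small enough to check
exhaustively, the greedy matching attains the same number of matches as
the optimal assignment (a property-tested invariant).

## 7. Numerical choices and problem sizes

* Erosion/dilation, the distance map, bilinear resize and the Gaussian
  blur are exact double-precision C++; equality against brute-force
  R oracles is asserted on integer-valued images.
* The CNN runs in single precision (the GEMMs dominate cost); determinism
  holds bitwise within a platform/BLAS.
* Patch sums of squares for the degree map come from a summed-area table,
  exact for integer-valued images.
* Test and acceptance problem sizes — 400 training patches, 100 held-out
  patches, 10–20 phantoms of 400x400 px with two masses, swarms of 8
  particles and 6 iterations in the end-to-end runs (20x20 where the
  optimizer itself is being measured) — were chosen as the smallest sizes
  at which every stage's behaviour is measurable and stable.
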