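---
title: "Adversarial segmentation of hippocampal subfields: model, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial segmentation of hippocampal subfields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adverseg)
```

## The problem

The hippocampus subdivides into small, morphologically intricate subfields
(CA1–CA3, dentate gyrus, subiculum, entorhinal cortex, parahippocampal
gyrus, plus head and tail regions) whose volumes track neurodegenerative
disease. Segmenting them from MR images is hard precisely because the
structures are small and their boundaries weakly contrasted: a per-pixel
classifier that ignores the spatial coherence of anatomical labels produces
speckled, implausible label maps.

`adverseg` implements an adversarial approach to this problem. A generator
network maps a 2D slice to a per-pixel class probability map; a second
network — the adversary — sees (image, label map) pairs and estimates the
probability that the label map came from an expert rather than from the
generator. Because the adversary aggregates evidence over its entire field
of view, it penalizes exactly the higher-order label statistics (spatial
consistency, boundary smoothness) that per-pixel losses cannot express, and
training the two networks against each other pushes the generator toward
label maps that are both pixel-accurate and globally plausible.

## The objective

For slices $x_n$ with expert label maps $y_n$, generator $g(\cdot)$ with
parameters $\theta_g$ and adversary $a(\cdot,\cdot) \in (0,1)$ with
parameters $\theta_a$, the hybrid objective is

$$
\ell(\theta_g, \theta_a) = \sum_{n=1}^{N} \ell_{mce}(g(x_n), y_n)
  - \bigl[\, \ell_{bce}(a(x_n, y_n), 1) + \ell_{bce}(a(x_n, g(x_n)), 0) \,\bigr]
$$

with the multi-class cross-entropy
$\ell_{mce}(\hat y, y) = -\sum_{i=1}^{H \times W} \sum_{m=1}^{M} y_{im} \ln \hat y_{im}$
and the binary cross-entropy
$\ell_{bce}(\hat a, a) = -[a \ln \hat a + (1-a)\ln(1-\hat a)]$.
The generator descends $\ell$ in $\theta_g$; the adversary ascends it in
$\theta_a$, equivalently descends the binary classification loss
(`adversary_training_loss()`). The generator's own training loss
(`generator_training_loss()`) uses the standard non-saturating substitution:
instead of minimizing $-\ell_{bce}(a(x, g(x)), 0)$ it minimizes
$+\ell_{bce}(a(x, g(x)), 1)$, which has the same fixed points but much
stronger gradients while the adversary still wins easily.
`combined_objective()` evaluates the hybrid objective literally, for
diagnostics and for oracle tests.

Probabilities are clamped to $[10^{-12}, 1]$ inside logarithms; the raw
formulas are undefined at exact 0/1 and the clamp bound is far below any
probability a finite-logit softmax or sigmoid can produce.

## The generator (UG-net)

The generator is a U-net variant with **one** 3×3 zero-padded convolution
per block instead of the usual two, halving the parameter count to resist
overfitting on small datasets. `depth` pooling levels halve resolution and
double channels on the way down; the decoder mirrors them with
nearest-neighbour upsampling, concatenation of the matching encoder feature
map (the skip connection that re-injects local detail), one convolution,
and dropout. The head is a 3×3 convolution to $M$ channels with a per-pixel
softmax.

Choices the architecture description leaves open, and what this package
does:

* **Head channels.** Training with $\ell_{mce}$ over $M$ classes requires an
  $M$-channel probability output, so that is the default head. A
  `single_channel` head mode — one label image via argmax — exists for
  export and visualization only; $\ell_{mce}$ is undefined on it.
* **Upsampling operator.** Nearest-neighbour interpolation followed by a
  convolution, rather than transposed convolution, avoiding checkerboard
  artifacts.
* **Nonlinearity and dropout.** Rectified linear units; dropout rate 0.5 on
  decoder blocks, active only in training mode.
* **Channel widths.** Unspecified at full scale; `generator_arch()` defaults
  to depth 4 with 64 base channels. The desk preset
  (`desk_generator_arch()`) uses depth 3 with 8 base channels — small
  enough that the full stochastic benchmark below runs on one CPU core in
  minutes, while keeping the architecture's structure (skips, dropout,
  softmax head) intact.
* **Input geometry.** Inputs whose sides are not divisible by
  $2^{\text{depth}}$ are rejected with instructions to pad or crop, rather
  than silently resized: slice-to-volume geometry must stay exact for
  volume-level evaluation.
* **Input scaling.** Images enter the network divided by 255, i.e. on
  $[0, 1]$ — standard conditioning.

## The adversary

The image and the label map are first processed by two separate
single-convolution branches with the *same* channel budget (32 each by
default), so neither signal dominates, and concatenated into a 64-channel
representation. A trunk of 3×3 convolution + rectifier + 2×2 max-pool
stages (64→128→256 channels by default; only the concatenated width is
prescribed, the trunk is a package choice) is followed by global average pooling
and a dense layer to a single sigmoid probability. Global pooling gives the
score a field of view covering the whole image by construction — the
property that lets the adversarial term penalize global label statistics.

Expert label maps are fed one-hot; generated maps are fed as the **soft**
probability map $g(x)$. Feeding an argmax-hardened map would sever the
gradient path from the adversary's verdict back into $\theta_g$, which the
generator's training loss requires.

## Training

`train_alternating()` runs the minimax loop: per cycle, `ratio` adversary
updates on fresh uniformly-sampled batches at a fixed learning rate, then
one generator update at the scheduled rate, until the generator has been
updated `total_generator_iterations` times ("iterations" counts generator
updates). `ratio = 0` trains the pure UG-net baseline on $\ell_{mce}$
alone. The optimizer is SGD with momentum (velocity form,
$v \leftarrow \mu v + (\nabla + \lambda_{wd}\,\theta)$,
$\theta \leftarrow \theta - \eta v$; weight decay coupled into the
gradient).

The full-scale defaults in `training_config()` are the published recipe:
batch size 5, momentum 0.99, weight decay $10^{-4}$, generator learning
rate $10^{-5}$ halved every 5000 iterations, adversary fixed at $10^{-5}$,
3 adversary batches per generator batch, 100,000 generator iterations.

Two numerical choices matter and are deliberate:

* **Gradient normalization.** The objective is a sum over pixels and
  samples, so its raw gradient scales with $H \times W \times$ batch size.
  Updates therefore descend the *mean* gradient (per pixel and per sample
  for the generator; per sample for the adversary), making step sizes
  independent of image and batch size. Loss *values* — in histories and in
  the exported loss functions — remain the plain sums the formulas define.
  In our desk-scale experiments, raw summed gradients under the full-scale
  recipe either oscillated without converging or collapsed to the
  background class.
* **Desk learning rates.** The published rate is tied to the published
  100,000-iteration schedule. `desk_training_config()` shortens the
  schedule roughly 200-fold and raises both learning rates to 0.01 to
  compensate; everything else (momentum, decay, batch size, 3:1
  alternation, halving schedule) is kept.

Further loop conventions: batches are drawn uniformly with replacement
(no epoch structure is prescribed); the adversary's 3 batches per cycle are
3 *distinct* fresh draws; generated maps for adversary updates come from
the generator in inference mode (deterministic, dropout off), while the
generator's own update uses training mode so the dropout noise it must be
robust to is part of its gradient. An optional scalar `lambda_adv`
(default 1, the objective's implicit weight) scales the adversarial term.
A non-finite loss aborts with the step index rather than training on.
Every random draw — initialization, batch order, dropout — flows from
`config$seed` through one RNG stream, so runs are bit-reproducible.

## Synthetic phantoms

Real subfield MR data with expert labels cannot ship with a package, so all
testing runs on synthetic phantoms that emulate the *layout* of such a
dataset: per-subject ROI volumes (default 112×103×24 voxels, matching the
ROI used for hippocampal subfield protocols), 24 axial slices per subject, intensities on
[0, 255], 9 foreground classes plus background.

Geometry is nested ellipsoids: foreground class with size rank $r$ occupies
the shell between its ellipsoid and the next smaller one, with shell voxel
budgets decreasing strictly in rank ($w_r \propto (K-r+1)^2$). This
reproduces the key difficulty of the real task — Head and CA1 are large
while CA2 and CA3 are small — without pretending to anatomical realism.
Per-subject seeded jitter moves centres and radii slightly. Intensity is
the class mean (background 10, foreground evenly spaced on [80, 240])
plus Gaussian noise (sd 5 by default) clipped to [0, 255].

Augmentation (`augment_slice()`) applies a random rotation (±10° default),
translation (±5 px) and Gaussian intensity noise (sd 5); magnitudes are
package defaults; the method prescribes the operations but no magnitudes. Images are resampled bilinearly, label maps with nearest-neighbour
(labels can never be invented), out-of-frame pixels get background label
and a configurable fill intensity (default 0, the background of normalized
images). A transform that would wipe out the entire foreground is redrawn
up to a bounded number of times, then errors. The corpus builder takes an
explicit integer `factor` (copies per base slice) plus an optional
`target_total` that truncates deterministically: reference corpora of this
kind report augmentations (768 → 5500 slices) that imply a non-integer
expansion whose recipe is not stated, so it stays configuration rather
than inference.

What the phantoms do *not* emulate: anatomical shape, MR physics, bias
fields, partial-volume boundaries, inter-rater label noise. Passing the
benchmark below therefore demonstrates that the pipeline — losses,
gradients, alternation, evaluation — works end to end on a separable task
of realistic geometry and class imbalance; it says nothing about accuracy
on real MR data.

## Evaluation

The Dice similarity coefficient
$\mathrm{DSC}(S_1, S_2) = 2|S_1 \cap S_2| / (|S_1| + |S_2|)$ compares
binary masks. Segmentation runs slice-wise, but scoring is **volume-level**:
predicted slices are stacked back into a 3D volume and each class's 3D
masks are compared — a per-slice mean would weight slices equally
regardless of how much of a structure they contain. Conventions:

* Argmax ties in prediction resolve to the lower class index
  (deterministic output).
* Both-masks-empty returns DSC 1.0 (vacuously perfect) and is flagged in
  the report, so fold averages stay finite while remaining auditable.
* "Overall" is the DSC of the whole-structure mask (union of all
  foreground classes), the quantity whole-hippocampus methods report; a
  size-weighted per-class mean is also reported, clearly labelled.

`crossvalidate()` splits **subjects** (never slices) into folds of
near-equal size; augmented samples inherit their base subject's fold, so no
augmented copy of a validation subject can leak into training. The fold
count is a parameter (reports of this method mention both tenfold and
fivefold protocols; default 10).

## The desk benchmark

`run_phantom_benchmark()` is the package's self-contained experiment:
8 subjects of 64×64×8 voxels, 3 classes (background + one large + one
small compartment), intensity noise sd 5, desk presets, 6 training / 2
held-out subjects, 200 generator iterations (~2–3 minutes adversarial,
~30 s baseline on one core). The problem sizes were chosen once as the
smallest configuration that still exercises multi-class imbalance,
hold-out evaluation and the full 3:1 adversarial loop. Typical held-out
mean foreground DSC is ≈ 0.98 for both the adversarial model and the
baseline — the phantom task is nearly separable by intensity, so the
benchmark checks that training *works*, not that adversarial training
*wins*; at this scale the two are statistically indistinguishable, and the
acceptance suite asserts non-inferiority (adversarial ≥ baseline − 0.02)
rather than improvement, which the method only demonstrates at full
scale on real data.

```{r benchmark, eval = FALSE}
res <- run_phantom_benchmark(seed = 1, adversarial = TRUE)
res$mean_foreground_dsc
res$reports[[1]]$per_class
```

## Known limitations

* No 3D convolutions: context along the depth axis enters only through
  volume-level evaluation, as in the slice-based original.
* The registration that precedes ROI extraction on real data is out of
  scope; inputs are assumed ROI-aligned.
* Full-scale training (depth-4/64-channel generator, 100,000 iterations)
  is supported by the code but is a GPU-days workload in any
  implementation; on CPU it is impractical, and the package's evidence for
  it is limited to the structural and oracle tests plus the desk-scale
  benchmark.
* With momentum 0.99 the effective step is ~100× the learning rate;
  the desk preset is stable under the mean-gradient normalization above,
  but aggressive custom configurations can still diverge (caught by the
  non-finite-loss guard).
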