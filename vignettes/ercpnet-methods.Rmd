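---
title: "Methods: channel expansion, adaptive attention and fusion for leaf-disease classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel expansion, adaptive attention and fusion for leaf-disease classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ercpnet)
```

## The problem and the model family

Leaf-disease classification from RGB photographs is a fine-grained
multi-class problem: lesions are small, their colour and texture carry most
of the signal, and healthy tissue dominates the frame. The networks in this
package attack that with three components, assembled as
stem → 3 × (expansion stage + attention) → fusion head → classifier.

**Stem.** A 7×7 stride-2 convolution (3 → `stem_width` channels, batch norm
+ ReLU) followed by a 3×3 stride-2 max pool. Spatial resolution is
quartered before the expensive stages. The pooling window is a design
choice (3×3, stride 2, padding 1 — the conventional companion of a 7×7
stride-2 stem).

**CER stage.** Each stage triples channel width and halves resolution. The
expansion itself is parameter-free: three max-pooling branches with
windows 3/5/9 (stride 2, paddings 1/2/4 so all branches agree spatially)
are concatenated along channels, widening the receptive field at three
scales simultaneously. An aggregation path (1×1 → 3×3 → 1×1 convolutions
at the expanded width, conv → BN → ReLU ordering) learns to mix the three
scales, and a stride-2 1×1 projection of the block input supplies the
residual, added before a final ReLU. With `stem_width = 16` the channel
progression is 16 → 48 → 144 → 432. Two points were genuinely open and are
resolved as follows: the strides are 2 on all three pooling branches *and*
the residual projection (the tensor-size contract halves resolution at
every stage, which a stride-1 reading cannot produce), and the aggregation
convolutions keep the expanded width 3C so that tripling is attributable
to pooling alone, never to a widening convolution.

**ACA attention.** After each CER stage, a channel gate and a spatial gate.
The channel gate pools the map into average and max per-channel
descriptors, passes both through the *same* pair of 1D convolutions
(single lane, same padding, ReLU between, no channel reduction), sums the
branches and applies a sigmoid. The kernel size of those convolutions is
not tuned by hand; it is computed from the channel count C by inverting
the Gaussian density at the normalised channel count \(y = C/N\):

\[
x = \sqrt{-2\sigma^2 \ln(y\,\sigma\sqrt{2\pi})} + \mu ,
\]

rounded to the nearest odd integer (ties away from zero) and floored at 1.
Odd kernels give symmetric padding; the floor honours the requirement that
the size be an integer of at least 1. The identification of \(y\) with a
raw channel count cannot be meant literally — for any usable \(\sigma\)
the logarithm's argument would exceed 1 — so \(y\) is taken as
\(C/N\) with a configurable normaliser, default \(N = 2048\), giving a
valid domain of C ≤ 817 at the default \(\sigma = 1\) and kernel sizes
3/1/1 at the default widths 48/144/432. Out-of-domain channel counts
raise an error naming the offending count rather than silently clamping.

The spatial gate stacks the channel-wise mean and max maps into two
channels and applies one 7×7 convolution and a sigmoid.

How the two gates combine is the one place where the formula and the
diagram of record disagree: the block is written additively
(\(F' = F + \sigma(\cdot) + M_S(F)\)), but the CBAM lineage and the
diagram imply sequential multiplicative gating. The default here is
multiplicative with the residual,
\(F' = F + M_S(w \odot F)\odot(w \odot F)\), because additive attention
cannot *suppress* a channel (a gate in (0,1) added to F moves every value
up), while the residual keeps an exact identity path for gradients. The
literal additive form is available via `combination = "additive"` and both
are tested. Weight sharing across the avg/max branches mirrors the shared
MLP of CBAM; a ReLU sits between the two 1D convolutions and nothing after
them (the sigmoid follows the branch sum).

**CBAM baseline.** For ablations, the classical block: a shared two-layer
perceptron (C → C/r → C, r = 16) channel gate and the same 7×7 spatial
gate, applied sequentially and multiplicatively, without a residual.

**BIF head.** The classifier should see pixel-level as well as semantic
information. The deep stage output P₃ (432×13×13 by default) is upsampled
×2 (nearest by default; bilinear available) and concatenated with the
mid-stage output P₂ (144×26×26); the merge is downsampled by a 3×3
stride-2 max pool and concatenated with P₃ again. Pure concatenation
yields 1008 channels, but the architecture's printed contract requires
1296 = 3·C₃; no concatenation arithmetic recovers that number, so a
trailing 1×1 convolution (+ BN + ReLU) performs the expansion, with
`out_channels` configurable. This is the one place where the published
wiring is not recoverable from its description; the trailing convolution
is the minimal completion that satisfies the contract.

**Head.** Global average pooling and one fully connected layer. The
softmax is applied at inference; training consumes logits through the
cross-entropy loss, the numerically standard arrangement.

## Training procedure

Mini-batch SGD, batch 16, momentum 0.9, weight decay 1e-4, initial
learning rate 0.01, cross-entropy loss. After each epoch the validation
accuracy is monitored; when it fails to improve for 3 consecutive epochs
the learning rate is multiplied by 0.3 (floored at 1e-8) and the stale
counter resets. "Improve" means strictly greater than the best seen so
far — comparing against the best, not the previous epoch, because the
alternative decays on any oscillation even while the trend improves. The
checkpoint retained at the end is the one with the highest validation
accuracy. All randomness (initialisation, data order, augmentation draws)
derives from explicit seeds, and evaluation-mode forward passes use batch
norm running statistics, so identical seeds give bitwise-identical
histories.

Evaluation reports accuracy = trace/total of the confusion matrix and
one-vs-rest precision/recall per class; averaged values are unweighted
(macro) by default, with support-weighted averaging behind
`average = "weighted"`. A class with a zero denominator (never predicted,
or absent from the truth) reports 0 and is flagged as degenerate rather
than producing NaN.

## Data handling and the synthetic generator

`load_image_folder()` reads a class-per-directory tree, resizes to the
network input size, and sorts classes and files in byte order so loading
is reproducible. `split_dataset()` splits 6:2:2 *per class* (stratified):
each class is shuffled under the seed, ⌊0.2n⌋ items go to validation and
to test, and the remainder to training — floors to the evaluation splits
so that training never starves. Augmentation applies, in order, a
horizontal flip (p = 0.5), a vertical flip (p = 0.5), a rotation drawn
uniformly from [0, 35] degrees and additive Gaussian pixel noise, then
clips to [0, 1]. The unspecified knobs are fixed at conventional values:
flip probabilities 0.5, noise σ = 0.01 of the dynamic range, bilinear
rotation resampling with edge-value fill (implemented in-package; constant
background fill would paint false borders on a leaf image).

The synthetic generator exists so that every module is exercisable without
downloads. Each image is a leaf-like green ellipse (jittered centre, axes
0.33–0.40/0.25–0.32 of the side, orientation) on a soil-toned noisy
background, stamped with the class's lesion motif: spots, rings or stripes
(cycling by class), in a class-specific colour with 4–7 lesions of radius
0.07–0.13 of the image side. Default lesion hues are confined to a
non-green band (hue ∈ [0.55, 1.25) mod 1) so diseased tissue is
chromatically distinct from healthy tissue — as real chlorotic and
necrotic lesions are — and lesion salience is set so that a plain
colour-histogram nearest-centroid classifier separates the classes
(>0.9 held-out accuracy), which the test suite verifies with an
independent implementation. What the generator does *not* emulate:
photographic texture, illumination variation, occlusion, background
clutter, within-class lesion heterogeneity. Passing tests on these images
demonstrates that the architecture, gradients and training loop are
correct and that the pipeline can fit and generalise on a separable
problem; they say nothing about accuracy on field photographs.

## Numerical choices and degenerate inputs

* Convolution is im2col + BLAS matrix multiplication; gradients are exact
  analytic transposes (scatter-add), verified against central differences
  at 1e-9–1e-4 tolerances in the suite.
* Batch norm uses ε = 1e-5 and running-statistic momentum 0.1; convs
  followed by BN carry no bias (the BN shift absorbs it), convs without BN
  do.
* Max pooling pads with −∞ so padding can never win; ties take the first
  position, fixing the subgradient deterministically.
* Initialisation is fan-scaled Gaussian (He-style for conv/ReLU layers),
  seed-controlled.
* Softmax subtracts the column maximum; the loss clamps probabilities at
  1e-300 before the log; a non-finite loss aborts with the epoch and
  learning rate named.
* Grad-CAM differentiates the *logit*, not the softmax probability, so the
  heatmap is invariant to constant logit shifts; a constant class
  activation map normalises to all zeros rather than 0/0.
* `igpdf_kernel_size` treats arguments within 1e-12 of the domain boundary
  as exactly 1 (radicand 0) to absorb rounding in user-supplied
  normalisers.

## Problem sizes used in the checks

The shipped checks run the full 416×416, 38-class network only for the
single-pass shape trace; training-path checks use reduced instances of the
same architecture (input 32–64 px, stem width 2–4, 2–4 classes, tens of
images, ≤ 50 epochs), which exercise every code path at a few hundred
thousand parameters. The overfit check — a 2-class, 32-image synthetic set
driven to training accuracy 1.0 — is the standard end-to-end gradient
sanity test for a training harness; the histogram-separability oracle
justifies that accuracy 1.0 is attainable.

## Known limitations

* The engine is single-threaded base R: fine for the reduced instances and
  one-image inference at 416×416 (seconds), not for full-dataset training
  at native resolution.
* Batch-norm statistics are per-batch with no synchronisation options;
  very small batches give noisy normalisation (the smoke tests use batch
  16 or full-batch).
* `num_stages` other than 3 changes the fusion head's inputs to the last
  two stages; the printed 416-pixel contract applies to the default
  configuration only.
* The additive attention mode is provided for completeness of the ablation
  surface; the multiplicative default is the mode all end-to-end checks
  train with.
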