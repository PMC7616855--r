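---
title: "Probing spatial-arrangement use in convolutional classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing spatial-arrangement use in convolutional classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(erfscope)
```

## The question the package operationalizes

Convolutional classifiers can in principle recognize objects in two very
different ways: by accumulating evidence from local surface statistics
(texture), or by exploiting the spatial arrangement of parts (shape). The
package provides a complete, desk-scale toolkit for separating these two
strategies: a family of residual classifiers whose theoretical effective
receptive field (ERF) is controlled exactly, a feature-scrambling probe that
destroys spatial arrangement while preserving local content, per-class
scrambling-sensitivity statistics, representational similarity analysis
(RSA), and a minimal-recognizable-configuration (MIRC) patch search.

## ERF-controlled architectures

All networks are four-block bottleneck residual CNNs: blocks of (2, 3, 3, 2)
units with widths (128, 256, 512, 1024) and strides (2, 2, 2, 1). Each unit
is a 1x1 -> kxk -> 1x1 convolution stack with a shortcut; the middle filter
size k per unit is the only knob that differs between variants, giving last
layer ERFs of 11, 23, 47, 95 or 227 pixels (`erf_variant_kernels`).

Receptive-field arithmetic is the standard forward recursion: a layer with
kernel k grows the ERF by `(k - 1) * jump`, where `jump` — the input-pixel
spacing of adjacent units — is multiplied by each layer's stride. Two
conventions make the arithmetic come out at exactly those five values, and
the package treats them as normative:

* a 3x3, stride-1 stem convolution precedes block 1;
* each block's stride sits on the *first 1x1* convolution of its first unit
  (before the kxk layer), so the stride multiplies `jump` before the middle
  kernel contributes.

No other structural option (stride on the kxk layer, no stem, strided stem)
reproduces all five printed ERFs simultaneously. `compute_erf()` returns
the full per-layer table (ERF, jump, feature-grid side); `erf_empirical()`
cross-checks it on any built network by a gradient-support probe: weights
are replaced by their absolute values and batch normalization is frozen at
(mean 0, var 1) with a small positive output shift, so every activation is
strictly positive, no ReLU can cut a path, and the bounding box of non-zero
input gradients of a centered last-layer unit is exactly the theoretical
receptive field. This probe requires an input larger than the analytic ERF;
on clipped inputs it reports the clipped support.

Choices the architecture leaves open (normalization scheme, stem width,
initialization) follow common residual-network practice: batch
normalization after every convolution, a 64-channel stem scaled with the
width multiplier, He-uniform seeded initialization, GAP -> fully connected
-> softmax head. None of these affects any ERF value. The width multiplier
exists for parameter-matched controls: `match_width_multiplier()` finds the
multiplier at which a small-ERF variant matches the parameter count of the
largest variant (within 1%, since counts are quadratic in width and
rounding is to whole channels).

## The training engine

No deep-learning backend is assumed: the package ships a compact CPU engine
(im2col convolution via Rcpp/Armadillo, batch normalization, SGD with
momentum 0.9). The training schedule holds the learning rate at 0.01 for 10
epochs and then decays it exponentially; the decay rate (default 0.94 per
epoch), batch size (default 128; 32 in the desk-scale studies) and
batch-norm momentum (0.9) are configuration fields. Gradients of every
layer are verified against finite differences in the test suite.
Preprocessing follows the central-square-crop -> resize-256 -> random-flip
-> random-224-crop pipeline, with the two sizes exposed as arguments; the
synthetic studies generate images directly at the network input size and
skip augmentation.

## The scrambling probe

A trained base network is frozen, its head detached, and its final
convolutional feature grid fed through an optional spatial permutation into
a trainable follow-up stack (four bottleneck units) with its own GAP +
softmax head. Two follow-up types bracket the hypothesis space:

* **aggregating** — 3x3 middle filters, stride 2 on the first two units:
  can integrate across space (composed ERF 235 for the smallest base, so it
  covers a 224 input);
* **pointwise** — only 1x1 convolutions, no downsampling: provably
  invariant to any spatial permutation of its input (the package asserts
  this to `1e-4` in logits, and it holds to machine precision).

The follow-up units are bottlenecks with the stride on the first 1x1, the
same convention as the base; this is what makes the composed ERF come out
at 235. The follow-up width defaults to the base's output width.

Permutations are bijections over grid cells, global or within
non-overlapping square windows (default side 2; remainder tiles at edges
are permuted among themselves, so no feature ever moves farther than
`window - 1` cells). Train-time scrambling draws one permutation and holds
it fixed across all updates; test-time scrambling redraws per image from a
seeded stream, because the variance of per-image draws is then averaged
over the test set. Scrambling always acts on the base's final feature grid,
before any pooling.

Since the base is frozen and the desk-scale studies use no augmentation,
composed models are trained on cached base features — mathematically
identical to forwarding every batch through the frozen base, at a fraction
of the cost.

## Per-class statistics

`evaluate()` computes one-vs-rest precision/recall/F1 from top-1
predictions. The scrambling ratio of a class is F1 after / F1 before
test-time global scrambling, computed only for classes the model reliably
classified before scrambling (F1 > 0.75); a class whose F1 collapses to 0
gets ratio 0, which is well-defined because eligibility guarantees a
positive denominator. Ranked ratio lists feed `class_set_overlap()`, the
pairwise intersection count of the k most/least sensitive classes across
models.

## RSA

First-order RDMs are pairwise correlation distances (1 − Pearson) between
flattened activation vectors; spatial grids are flattened per stimulus,
which is the standard RSA convention. The probed layers are the outputs of
all 10 residual units plus GAP and softmax — 12 per model, hence a 60x60
second-order RDM across the five variants, built from correlation distances
between vectorized upper triangles. Explained variance between two RDMs is
the squared Pearson correlation of their upper triangles (Spearman would be
the robust alternative; Pearson is fixed here and stated). RDM averaging
across seeds is element-wise and preserves symmetry, hollowness and range.

`mds_embed()` uses classical (Torgerson) metric scaling rather than an
iterative stress minimizer: it is deterministic without a seed, exact on
Euclidean-embeddable dissimilarities, and the embedding only serves
visualization. The residual stress of the embedding is attached so a caller
can judge distortion. `sensitivity_contrast()` implements the repeated
class-sampling contrast (default 100 repetitions, 20 images per class) as a
function of two arbitrary feature extractors, so constructed-representation
fixtures and real models use the same code path.

## MIRC search

The search starts at a correctly classified full image; every correct patch
spawns four corner-anchored descendants spanning 75% of its height and
width. Crops are upsampled to the model's input size with bilinear
interpolation before classification. Descendant sides use `floor(0.75 *
side)` clamped to one pixel; a no-progress guard stops recursion when a
descendant equals its parent, and a configurable level cap (default 10)
bounds the tree, with capped leaves flagged separately from true MIRCs.
"Correct" means top-1 agreement with the true class, with no probability
threshold. Overlapping descendants can repeat a bounding box; those are
evaluated once (memoized) but counted as distinct leaves, so leaf counts
match the 4^L combinatorics of the search tree. For visualization, the
reported representative of an image is its deepest MIRC, ties broken by
class probability. MIRC clustering takes GAP vectors of the upsampled
patches, runs seeded k-means (k reduced with a warning when there are fewer
distinct latents), and reports per cluster the nearest-to-center exemplars
constrained to distinct source images.

## Synthetic data: what it emulates and what it does not

The generator produces the two cue regimes the probe is designed to
separate, at a scale where every experiment runs on one CPU:

* **Texture classes** are oriented stripe patterns (orientations evenly
  spaced over 180 degrees, period 8 px, random phase per image, Gaussian
  noise sd 0.08). Any patch larger than one period is class-diagnostic, so
  these classes are scrambling-insensitive by construction.
* **Arrangement classes** place the *same* three glyphs (bar, disk, cross;
  13 px) along a chain whose orientation — horizontal, vertical, diagonal,
  anti-diagonal — defines the class. Part order along the chain is random
  per image, each part is jittered by ±2 px, and the whole layout is
  translated uniformly over the toroidal canvas (glyphs wrap around edges).
  Part-occurrence histograms are therefore identical across classes, every
  part is equally likely at every position, and only relative spatial
  configuration carries class identity.

Two design choices deserve their rationale. First, translation is uniform
over the full torus rather than a small jitter: spatial-arrangement
learning is only distinguishable from pattern memorization when the set of
distinct cell-level configurations is large relative to the training set.
With the 8x8 feature grid of a 64-px network, a ±few-pixel jitter yields
fewer than ten distinct cell-occupancy patterns per class, which a
follow-up network can memorize even through a fixed permutation; toroidal
translation yields 64 per axis. Wrapping never destroys the class cue: at
most one adjacent part pair is cut per axis, so at least one intact pair
always witnesses the chain orientation. Second, chain spacing (16 px)
exceeds the glyph side (13 px), so parts never collide and no local overlap
artifact can leak class information; because the geometry guarantees
clearance, no rejection-resampling of layouts is needed.

Two baselines certify the cue separation at generation time:
`texture_patch_baseline()` (nearest-centroid on patch orientation-energy
features) must exceed 95% on texture classes, and
`bag_of_parts_baseline()` (nearest-centroid on template-matching detection
counts, positions discarded) must sit at chance — within a 99% binomial
confidence interval — on arrangement classes. The detector is normalized
cross-correlation with greedy peak suppression; its counts can leak a
percent or two of class information through orientation-dependent partial
matches, which is why the certification band is a CI around chance rather
than exact equality; the ground-truth count table is exactly constant by
construction. The sketch mode blurs lightly (Gaussian sigma 0.8),
thresholds the gradient magnitude at 0.15 and renders black contours on
white, turning filled glyphs into outlines.

What the synthetic regimes deliberately do not emulate: natural image
statistics, intra-class shape variability, occlusion, scale and viewpoint
changes, or the content of any published dataset. Passing the desk-scale
study therefore shows that the *machinery* — scrambling, composition,
per-class statistics — detects arrangement-dependence when it is the only
available cue; it does not certify conclusions about any natural dataset.

## The desk-scale cue-separation study

The study conditions are fixed once: 64-px grayscale images, 4 texture + 4
arrangement classes, 200 images per class (75/25 train/test), the
smallest-ERF (11 px) variant at width multiplier 1/16 as base, follow-up
width equal to the base output width, base trained 8 epochs and follow-ups
25 epochs at batch size 32, three seeds. The two cue types are combined
into one 8-class task: this mirrors per-class analyses on heterogeneous
natural datasets, and it is what gives the base network a real training
signal (texture classes) while leaving it at chance on arrangement classes
— its GAP head sees identical part histograms. Chance for the arrangement
group is taken as 1/4, uniform guessing among the four layouts, because
cue-type identity (stripes everywhere vs. sparse glyphs) is itself a local
cue that scrambling does not remove.

The acceptance suite asserts, averaged over the three seeds: test-time
global scrambling collapses the arrangement group to chance (within 10
points) while the texture group retains at least 80% of its unscrambled
accuracy; a follow-up trained on a fixed permutation fully recovers the
texture classes while its arrangement-class drop strictly exceeds the
texture drop and is expected to reach 20 points; and window-2 local
scrambling degrades arrangement strictly less than global scrambling.
These are directional, property-style assertions — desk-scale analogs, not
reproductions of any dataset-specific percentage. The 20-point band is the
strictest of them: the train-scrambled model keeps some arrangement skill
by partially memorizing the finitely many cell-level layout variants a
64-px canvas can produce, so that band sits at the edge of what this scale
can show (see the limitations below).

## Numerical and degenerate-input conventions

* Batch-norm epsilon 1e-5; running statistics with momentum 0.9.
* Cross-entropy clamps probabilities at 1e-12; a non-finite loss aborts
  training with a diagnostic rather than propagating NaNs.
* A 1x1 grid has exactly one permutation (the identity); a local window of
  1 is the identity; a window larger than the grid falls back to global
  with a warning.
* `compute_rdm()` refuses zero-variance activation rows by name;
  `rdm_r2()` refuses constant triangles.
* Ties in top-1 prediction resolve to the lowest class index,
  deterministically.
* All randomness (weights, shuffling, permutations, sampling, generation)
  flows through explicit integer seeds; generation is bit-reproducible.

## Problem sizes

The test suite and the study above use 64-px images, width multiplier 1/16
(about 40k parameters), 1600-image datasets and three seeds — sizes chosen
so the full suite, including training, completes in tens of minutes on one
CPU core. The same code paths scale to the canonical 224-px,
multiplier-1 architectures; only time separates the two regimes.

## Known limitations

* The engine is CPU-only and single-threaded beyond BLAS; it is meant for
  desk-scale probing, not large-scale training.
* Fixed-permutation (train-time) scrambling is only informative when
  configuration diversity is large relative to the training set; with small
  canvases and narrow translation ranges the follow-up can learn the
  permuted task outright. The toroidal-translation design above exists
  precisely to keep the desk-scale study in the informative regime.
* F1-based rankings are computed from top-1 predictions; probability-aware
  variants (e.g. AUC-based sensitivity) are out of scope.
* Classical MDS can distort strongly non-Euclidean dissimilarities; the
  attached stress should be checked before interpreting an embedding.
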