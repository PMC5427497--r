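---
title: "Classifying protein subcellular localization in yeast microscopy: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying protein subcellular localization in yeast microscopy: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(yeastloc)
```

## The problem

High-throughput microscopy screens of GFP-tagged yeast strains produce
millions of single-cell images, each a two-channel 64x64 patch: a red
cytosolic marker outlining the cell body and a green channel showing where
the tagged protein accumulates.  The analysis task is to assign each cell
-- and, by aggregation, each protein -- to one of twelve subcellular
compartments (cell periphery, cytoplasm, endosome, ER, Golgi,
mitochondrion, nuclear periphery, nucleolus, nucleus, peroxisome, spindle
pole body, vacuole).  `yeastloc` implements the full analysis stack:

1. an 11-layer convolutional network trained on raw pixels,
2. a classic hand-crafted-feature baseline (intensity, geometry,
   Haralick, Gabor, Zernike families) with a random-forest classifier,
3. a random-forest quality filter separating cells from imaging artifacts,
4. Dirichlet--multinomial aggregation of per-cell class probabilities
   into per-protein compartment calls,
5. stratified-bootstrap evaluation (precision/recall CIs, Cohen's kappa),
6. transfer learning from intermediate network activations to unseen
   compartment classes, and interpretability tools (t-SNE embeddings,
   neuron--class mutual information, neuron--feature correlations,
   maximally activating patches).

Because the original screen images are large downloads, the package ships
a parametric synthetic microscopy generator that renders labelled
two-channel cells for every localization archetype.  All tests and the
bundled analyses run on this generator.

## The network

The classifier is a VGG-style stack: eight 3x3 convolutions at stride 1
with zero padding ("same"), each followed by batch normalization and a
rectified linear unit, with 2x2/stride-2 max pooling after designated
conv layers, then three fully connected layers (batch normalization and
dropout 0.5 on the first two).  The reference configuration uses conv
widths 64, 64, 128, 128, 256, 256, 256, 256, pooling after conv layers
2, 4 and 8, and FC widths 512, 512, 12; on a 64x64 input the three
poolings leave an 8x8x256 map, so the first FC layer sees 16,384 inputs.
`parameter_count_formula(network_config())` puts the learnable parameter
total at 10,987,788 -- conv weights and biases, FC weights and biases,
and batch-norm scales and shifts.

Training follows the standard recipe for this architecture: per-pixel
training-set mean subtraction, Glorot-normal initialization,
cross-entropy loss minimized by SGD with momentum 0.9, initial learning
rate 0.1 halved every 16,250 iterations (25 epochs at 65,000 training
images and batch size 100), weight decay 5e-4, dropout 0.5, and model
selection by validation loss over per-epoch checkpoints.

Implementation notes, all visible in `R/train.R` and `src/convops.cpp`:

* Convolution is im2col + GEMM.  Activations flow as (H, W, N, C)
  arrays, which makes the GEMM output reshape-identical to the next
  layer's input and keeps the conv stack transposition-free.
* Batch normalization operates on the (positions x channels) matrix
  view; for conv layers this normalizes per channel over batch and
  space.  Inference uses running statistics (momentum 0.9).  Because an
  epoch at desk scale is only a few dozen iterations, running statistics
  are noisy at checkpoint time; before each validation checkpoint the
  running statistics are therefore replaced by plain averages of batch
  statistics over a few class-interleaved batches ("precise"
  batch-norm).  This affects evaluation stability only, not the learned
  weights.
* Under batch normalization the conv/FC bias is algebraically absorbed
  by the batch-norm shift; the bias parameters exist (and are counted)
  but receive no updates.
* Inputs are divided by one global scalar (the training-set standard
  deviation) after mean subtraction.  This is numerical conditioning for
  the optimizer and the weight-decay penalty on 16-bit-scale
  intensities; the first batch-norm layer makes the model family
  invariant to it.
* Optional linear learning-rate warmup and global gradient-norm clipping
  are exposed in `train_config()`; the desk-scale preset uses both
  (warmup 20 iterations, clip 5) to protect the cold batch-norm
  statistics in the first iterations.
* Batch-norm placement follows "after each layer, before the
  activation"; we apply it to all conv layers and to FC-1 and FC-2 but
  not to the softmax layer, reading "each fully connected layer" as the
  hidden ones.  Pooling placement (after conv 2, 4, 8) is the 2-2-4
  block reading of the architecture diagram.  Both are recorded here as
  assumptions.

### Desk-scale preset

Full-scale training of the reference configuration is a multi-day GPU
job.  For a single CPU the package defines a desk preset
(`small_network_config()`): the same topology -- eight 3x3 convs, three
2x2 poolings, three FC layers -- with conv widths divided by 8 (8, 8,
16, 16, 32, 32, 32, 32), FC widths 64, 64, K, and the poolings moved
early (after conv layers 1, 2 and 8).  Early pooling shrinks the
full-resolution feature maps as soon as possible, which is where almost
all of the CPU time goes; with it, one training iteration at batch 50
takes well under a second, and a full desk-scale training run
(~900 training images, 12 epochs) takes two to three minutes.  The desk
preset also lowers dropout to 0.15: with 64-unit FC layers and a few
hundred training images, dropout 0.5 under-fits badly.  The reference
configuration remains available unchanged.

## The synthetic generator

`render_cell()` draws parametric cartoons of the localization
archetypes: soft-edged elliptical cells with an off-centre nucleus
(dimmed in the red channel), and a green-channel pattern per class --
a boundary ring (cell periphery), diffuse fill excluding the nucleus
(cytoplasm), a filled nuclear disk (nucleus), a crescent clipped by the
nuclear boundary (nucleolus), a thin annulus on the nuclear rim (nuclear
periphery), a perinuclear ring with radiating strands (ER), curvilinear
tubules (mitochondrion; also actin cables and microtubules among the
transfer classes), a rim with dark lumen (vacuole), a band at the
mother--bud junction (bud neck), and puncta for the punctate classes.

Two design principles matter for what the package can and cannot show:

* **Punctate classes are separated by spatial arrangement, not
  texture.**  Endosomes, Golgi, peroxisomes and spindle poles all render
  as puncta of the same size and brightness distribution, with
  overlapping count ranges; they differ in where the puncta sit
  (mid-radius on the anti-nucleus side; clustered around the nucleus;
  near the periphery; on the nuclear rim).  This mirrors the real
  difficulty -- punctate compartments are hard to tell apart from
  texture alone -- and gives pixel-level models access to information
  that global texture statistics cannot represent.
* **Nuisance realism.**  Each cell gets independent per-channel
  log-normal brightness jitter (sd 0.2), a random linear background
  gradient (150 a.u. peak-to-peak), Gaussian read noise (sd 100 a.u. on
  the 16-bit scale), signal-scaled Poisson noise (variance 2x intensity),
  one random defocus blur per cell (Gaussian sigma 0.4--1.6 px), a
  variable diffuse cytosolic pool diluting the pattern (5--40% of peak),
  segmentation centring error (+/-4 px), cell size variation (semi-axis
  15--24 px), and, with probability 0.75, one or two partial neighbour
  cells at the patch border carrying the same protein -- as in a real
  screen, where every cell in a well expresses the same tagged gene.

The defaults were calibrated once so that the two model families land in
the intended relative regime on a desk-scale dataset -- the classic
feature battery with a tuned random forest in the low-to-mid 0.7s of
test accuracy, the desk CNN at or slightly above it -- echoing the
ordering (deep network above classic features, both clearly below
protein-level aggregation) rather than any absolute numbers.  Defocus
blur, brightness jitter and centring error are the nuisances that
dominate this balance: they degrade co-occurrence contrast, filter-bank
energies and patch-centred moments (the features that otherwise solve
the cartoons outright) much faster than they degrade a convolutional
classifier.

What the generator does **not** emulate: realistic optics beyond
Gaussian blur, cell-cycle morphology, crowded colonies, uneven
illumination beyond a linear plane, or the label noise of manual
annotation.  Passing the ordering tests here therefore shows that the
implementation learns and evaluates correctly at desk scale, not that it
reproduces the accuracies reported on real screens.

All randomness derives from one master seed: per-cell seeds are
`derive_seed(master, counter)` with a multiplicative-congruential hash,
kept below 2^31; renders are bit-identical given (label, params, seed).

## Classic features and forests

Per channel and per scale (full resolution and 2x box-downsampled):
13 Haralick statistics from a 32-level, distance-1, 4-direction
symmetric co-occurrence matrix (whole-matrix normalized); mean absolute
response and energy of a DC-free Gabor bank (3 frequencies x 4
orientations); Zernike moment magnitudes to order 9 over the centred
half-patch disk; plus intensity summaries, Otsu-mask geometry, and
cross-channel correlation/ratio -- 296 features.  Exact reproduction of
the historical 435-feature CellProfiler battery is not possible from its
description; the families above are the documented approximation, and
the features-per-split grid is therefore rescaled to fractions of the
actual width (sqrt, 25%, 50%, 75%, 100%).

The baseline forest is selected by validation accuracy over a grid of
forest size, features-per-split and minimum node size (the full
5 x 5 x 5 reference grid, or a reduced 2 x 2 x 2 grid for desk runs).
The quality filter is a 100-tree forest discriminating rendered cells
from rendered artifacts (empty patches, low-signal cells, debris), with
10-fold cross-validation over features-per-split and over whether to
downsample the majority class.

## Protein-level aggregation

Each cell's softmax vector is treated as a soft assignment over
compartments; with a symmetric Dirichlet prior `alpha0` the protein's
posterior concentration is `alpha0 + sum of per-cell probability
vectors` (soft counting), the MAP compartment is the largest entry, and
`(alpha_k - alpha0) / sum(alpha - alpha0)` estimates the fraction of
cells in which the protein resides in compartment k -- which is how
mixed nucleus+cytoplasm proteins are reported via `top_k_classes()`.
"Uninformative" is read as the flat prior `alpha0 = 1` (exposed as a
parameter); under it the MAP over the simplex coincides with the largest
soft count, including for proteins observed in few cells.  Soft counting
uses full probability vectors, not per-cell argmax.

## Evaluation

Confusion matrices are rows = true, columns = predicted; accuracy is the
trace fraction and Cohen's kappa `(p_o - p_e)/(1 - p_e)` uses marginal
products for the expected agreement.  Bootstrap confidence intervals
resample (true, predicted) pairs with replacement *within each true
class*, so class counts are invariant across replicates; per-class
precision and recall are computed per replicate and the 2.5%/97.5%
percentiles form the 95% interval (percentile method, matching the
stated rule; not BCa).  Replicates in which a class receives zero
predictions contribute no precision value and are dropped before the
percentiles -- a documented convention for a case the percentile rule
leaves open.  The reference replicate count is 20,000; desk-scale tests
use 2,000 or fewer, which widens nothing but the Monte-Carlo error of
the interval endpoints.

## Transfer and interpretability

Four additional compartment classes (actin, bud neck, lipid particle,
microtubule) never seen by the network are classified from extracted
activations: random forests are fit on stratified subsamples of 1, 3, 5,
10, 25, 50, 100, 250 and 500 training images per class (the desk tests
use the <= 10 rungs), model-selected on validation data, and scored on
held-out data, separately for network features (first FC layer by
default) and classic features.  Convolutional activations are
global-average pooled per channel by default to keep forest inputs
tractable; flattened maps are available.

Interpretability: per-neuron mutual information with the class label
(equal-frequency 16-bin discretization with tied values sharing a bin,
in bits; for convolutional layers the MI is over individual map neurons,
subsampled for tractability, while transfer and correlation analyses use
the pooled per-channel summaries), strongest absolute
Pearson correlation to a classic feature, 2-D t-SNE embeddings of layer
activations (own exact O(n^2) implementation -- perplexity-calibrated
Gaussian affinities, Student-t kernel, early exaggeration, momentum
descent -- adequate at the 1,000-cell scale used), and maximally
activating input patches with receptive-field arithmetic (3x3 stride-1
convs add 2 x jump pixels; each pooling doubles the jump).

## Desk-scale study sizes

The ordering studies run per seed on: 12 classes x 8 proteins x 12 cells
(1,152 images; protein-level folds 6/1/1 per class), the desk network
preset trained for 14 epochs at batch 50 (initial learning rate 0.1,
halving every 150 iterations, warmup 20 iterations, gradient clip 5,
checkpoints with refreshed batch-norm statistics every 2 epochs), the
reduced forest grid, a 4-class transfer set of 40 cells per class
(16/8/16 per fold), and 2,000-replicate bootstraps.  These sizes are the
package's choice of a benchmark that a laptop CPU completes in a few
minutes per seed while leaving every ordering property measurable.
Because single-cell accuracy of the two model families differs by only
a few points at this scale, the network-over-baseline comparison is read
on the across-seed mean, not per seed.

## Known limitations

* The desk preset's accuracies are far below the full-scale regime; only
  orderings and monotonicities are meaningful at this size, and the
  CNN-over-baseline margin at desk scale is a few points, not the
  double-digit gap reachable with millions of parameters and tens of
  thousands of images.
* The synthetic archetypes are cartoons; none of the numbers here
  transfer to real micrographs.
* The t-SNE implementation is exact (quadratic); do not use it above a
  few thousand points.
* Training is single-threaded by design; identical seeds give identical
  runs on a fixed BLAS.
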