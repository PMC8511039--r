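---
title: "Multi-scale CNN classification of kidney histology slides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale CNN classification of kidney histology slides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pyramidwsi)
```

## The problem

Clear cell renal cell carcinoma (RCC) and clear cell papillary RCC overlap
morphologically on H&E slides but carry opposite prognoses, so telling them
apart matters clinically and is hard enough that it often requires expert
review or immunohistochemistry. `pyramidwsi` implements a pyramidal deep
learning pipeline that classifies kidney slide images into four tissue
classes — fat (1), renal parenchyma (2), clear cell papillary RCC (3) and
clear cell RCC (4) — plus a background code 0, and produces both patch-level
labels and a smoothed pixel-level classification map.

The pipeline has five stages:

1. **Patching.** The slide is decomposed into overlapping square patches at
   three scales (250, 350, 450 px). Training grids use 50% overlap
   (stride = size/2); inference grids use a dense 5-pixel shift so that every
   pixel is covered by many patches. Patches dominated by background
   (fraction of exact-background pixels > 0.5) are removed.
2. **Preprocessing.** Contrast limited adaptive histogram equalization
   (CLAHE), then edge enhancement by convolution with a constant-preserving
   sharpening kernel. The order is fixed.
3. **Classification.** One small CNN per scale (identical architecture,
   different input size) assigns each patch one of the four tissue classes.
4. **Aggregation.** Each classified patch votes for its label on every
   non-background pixel of its rectangle; per-pixel majority voting yields a
   label map per scale; the three maps are fused by per-pixel majority.
5. **Smoothing.** A generalized Gauss–Markov random field (GGMRF) prior is
   relaxed over the fused map to remove isolated inconsistencies.

## The network

Each CNN is four blocks of two 3×3 valid convolutions (9 filters, stride 1,
no padding) followed by a 2×2 stride-2 max-pool, then a 12-unit and a 4-unit
fully connected layer and a soft-max. A valid 3×3 convolution shrinks each
side by 2 and pooling halves it (flooring odd sides), so one block maps side
length $n \mapsto \lfloor (n-4)/2 \rfloor$ and the 250-input spatial chain is
248, 246, 123, 121, 119, 59, 57, 55, 27, 25, 23, 11, giving a flatten width
of $11 \cdot 11 \cdot 9 = 1089$. Counting kernel products only (bias-free), the model has
$5346 + 13068 + 48 = 18462$ weights; biases (88) are tallied separately.
Because of the floor rule the smallest admissible input is 76 (76 → 36 → 16
→ 6 → 1). `derive_schedule()` computes this chain analytically and
`cnn_trace_cpp` (used by the tests) verifies the built network reproduces it
at run time.

Training minimizes the multiclass cross-entropy
$L = -\sum_i y_{o,i} \log P_{o,i}$ with Adam (default learning rate 0.001,
batch 32, 60 epochs), holds out 20% of the training patches for validation,
snapshots parameters after every epoch, and returns the snapshot with the
highest validation accuracy (earliest epoch on ties). Augmentation applies
random rotations (90/180/270°), horizontal/vertical flips, and ±10% scale
jitter with center crop or replicate-pad back to the input size, after
preprocessing. Dropout at rate 0.2 regularizes the conv-stack output (the
flatten input) and the first fully connected layer.

### Numerical and optimization choices

These choices were made from optimization diagnostics on the synthetic
texture task; they are the package's own engineering and are all exposed as
parameters:

* **Activation: leaky ReLU (slope 0.01).** With hard ReLU, this very narrow
  architecture (9 filters per layer) loses units irrecoverably: once a
  channel's pre-activations go negative everywhere, no gradient ever
  revives it, and in practice whole layers died within tens of small-batch
  Adam steps.
* **Input centering.** 8-bit patches are mapped to $[-0.5, 0.5]$. Histology
  patches share a large positive DC component; uncentered, that common mode
  dominates every activation and the class contrast arrives at the head
  orders of magnitude smaller than the activations carrying it.
* **Zero-initialized output layer.** He initialization is used for the
  convolutional kernels and the first FC layer; the final FC layer starts at
  zero, so the network begins exactly at the uniform prediction. With a
  randomly initialized head, the quickest early loss reduction is to shrink
  activations toward the class prior — on small batches this collapses the
  whole feature extractor, a state the network cannot leave.
* **Exact head pre-fit, then discriminative rates.** Before the epoch
  loop, the FC head is fitted on cached flatten features with full-batch
  Adam for `warmup_steps` (default 300): the conv layers are frozen, so
  each training patch's features are computed once — together with its
  rotations/flips and two circularly-shifted copies, which permute the
  feature grid spatially and force the head onto pooled statistics, the
  property that lets it generalize from grid-aligned training patches to
  arbitrary offsets during dense inference. The subsequent end-to-end
  epochs train the conv layers at `conv_lr_scale` (default 0.1) times the
  head's rate, the usual fine-tuning arrangement. Mini-batch head warm-up
  was tried and abandoned: at desk-scale batch counts the gradient noise
  kept the head at the uniform prediction indefinitely, while the exact
  full-batch fit converges in tens of steps.
* **Model selection includes the pre-fit state.** The epoch snapshot with
  the best validation accuracy is returned, with the post-warmup state as
  the epoch-0 candidate, so a fine-tuning phase that degrades the model on
  a given fixture cannot ship.
* **Dropout placement.** Applying dropout after *every* max-pool made
  small-batch gradients so noisy that training stalled indefinitely at the
  uniform prediction; the implementation regularizes the conv-stack output
  and the first FC layer instead, at the same rate.
* Single precision is used in the compiled kernels; probabilities are
  floored at $10^{-12}$ before logs; soft-max subtracts the max logit.

## Aggregation and smoothing

`accumulate_votes()` adds, for each classified patch, one vote for its label
on every non-background pixel of its rectangle, using a corner-delta /
integral-image scheme whose cost is independent of patch size; background
pixels (exact equality with the background colour) are labelled 0 from the
start and never vote. Majority voting breaks ties toward the lower class id.
Scale fusion takes the per-pixel mode of the three scale maps; when all
three disagree the medium-scale map wins, since 350×350 is the
best-performing single scale.

The GGMRF smoother minimizes, at each pixel $s$ with observed label
$\delta_s$ and candidate label $c$,

$$ |\delta_s - c|^\alpha \;+\; \rho^\alpha \lambda^\beta
   \sum_{r \in \nu_s} \eta_{s,r} \, |\delta_r - c|^\beta $$

over $c \in \{1..4\}$, where $\nu_s$ is the 8-neighborhood and $\delta_r$
are the current neighbour estimates; sweeps run in raster order until no
pixel flips or `max_sweeps` is reached. Defaults are $\alpha = 2$,
$\beta = 1.01$, $\rho = 1$, $\lambda = 5$, $\eta = \sqrt 2$. Three details
deserve note:

* The pair term uses the neighbour difference $|\delta_r - c|^\beta$, the
  standard GGMRF form; a formulation that compared the centre label to
  itself would be independent of the neighbourhood and smoothing would do
  nothing.
* The potential $\eta_{s,r}$ is configurable; both the $\sqrt 2$ and the
  plain 2 reading of its published value can be set.
* The absolute difference $|i - j|$ on integer class codes makes class 1
  "closer" to class 2 than to class 4 even though the codes are nominal; a
  Potts-style 0/1 distance is available via `ggmrf_params(distance =
  "potts")`. The default keeps the absolute-difference potentials implied
  by the model's exponents.

Background pixels are frozen throughout and excluded from neighbour sums.
Sequential minimization of the local energy with symmetric pair potentials
never increases the global energy (data terms plus each unordered pair
counted once), which the test suite checks, along with fixed-point behaviour
and the hand-computed isolated-pixel example.

## Preprocessing details

CLAHE runs on the Rec.601 luma channel; each RGB pixel is then rescaled by
its luma gain, so chrominance ratios are preserved exactly and no hue shift
can occur (a cheaper route to the same goal as equalizing a Lab L-channel,
and exactly hue-preserving by construction). The tile decomposition
(default 8×8, relative clip limit 0.01) requires dimensions divisible by
the grid; inputs are replicate-padded to the next multiple and cropped
back. Equalization of a contrast-free (constant) patch returns it
unchanged. Sharpening convolves each channel with a configurable odd,
sum-to-one kernel (default Laplacian-sharpen
$[[0,-1,0],[-1,5,-1],[0,-1,0]]$; the published kernel lives in an
unavailable supplement and can be substituted from a CSV), with replicate
border padding to avoid halos, clipping back to 0..255.

One behavioural note: standard clip-limited equalization maps a level to
its (clipped) cumulative frequency, so a two-level checkerboard maps its
lower level toward mid-range rather than to 0 — the output range widens and
reaches the top of the dynamic range, but is not a superset of the input
range. The tests assert the former, true property.

## The synthetic slide generator

Clinical whole-slide images are private, so all tests run on synthetic
slides: seeded Voronoi partitions of the plane (irregular region boundaries,
like tumour margins) with tissue classes assigned round-robin, rendered with
per-class procedural textures on a pure-green background (the scanner
background convention), plus an optional background frame. By construction a
pixel is labelled 0 *iff* its colour equals the background colour exactly,
which is what the background-filtering and vote-masking stages key on.

The textures are base colour + stationary Gaussian texture (iid noise
and/or a smoothed field with a class-specific correlation length) +
optional sinusoidal pattern. Three design constraints shaped the defaults:

* **Classes are coded by chrominance and spatial structure, not
  brightness.** CLAHE renormalizes each patch's luminance histogram, so a
  brightness-coded class identity does not survive the pipeline's own
  preprocessing. The default classes differ strongly in RGB ratios (which
  the luma-gain CLAHE preserves exactly) and in spatial texture scale —
  fat is smooth (noise sd 5), parenchyma is fine speckle (sd 20), the two
  tumour classes carry smoothed-noise fields at well-separated correlation
  lengths (sigma 3 vs 8, amplitude 25) — which equalization cannot erase.
* **Textures are translation-stationary.** An earlier design used coherent
  global sinusoids; classifiers then latched onto the pattern phase at the
  training grid's offsets and confused classes wholesale at the dense
  inference offsets. Random-phase (smoothed-noise) textures remove the
  failure by construction.
* **Separability floor.** A 1-nearest-neighbour classifier on mean patch
  colour alone exceeds 0.9 accuracy on raw patches (a property test), so
  the CNN task is learnable at desk scale by construction.

What the generator does *not* emulate: nuclear morphology, stain variation,
scanner artifacts, spatially correlated noise, or class-ambiguous
transition tissue. Passing the end-to-end tests therefore demonstrates that
the pipeline's machinery — patching, preprocessing, training, voting,
fusion, smoothing — is correct and learns texture-distinct classes; it says
nothing about accuracy on clinical H&E.

## Desk-scale study conditions

The test suite and the acceptance script run the full pipeline at reduced
problem sizes chosen for single-CPU runtime: twelve training slides of
900×900 px with a 32 px background frame — eight single-diagnosis slides
(two per class, matching the clinical material, where each slide carries
one tissue type) plus four two-region slides so that mixed boundary
patches with majority labels are represented — a patch-level 70/30
train/test split capped at 100 patches per scale, 6 end-to-end epochs at
batch 8 and learning rate 0.01 after the 300-step head pre-fit, and a
held-out panel of four slides (two single-diagnosis, two with a tumour
boundary) classified with a 50 px inference shift (the dense 5 px
default remains in `pipeline_config()`; 50 px still covers every pixel
dozens of times at these scales). The generator defaults (1200×1200, four
regions) are what `fixtures generate` produces from the command line.
Pipeline smoke tests use surrogate scales (76/88/100 px) to exercise
orchestration cheaply; all accuracy claims run at the standard 250/350/450
scales.

## Where fusion helps and where it cannot

On the synthetic fixtures the single-scale label maps are essentially
perfect inside class regions; their errors live in bands along region
boundaries whose width grows with the patch size, because a patch casts
one vote for its majority class over its whole rectangle. The three
scales' error sets are therefore nested rather than independent, and
per-pixel majority fusion can only tie the small scale inside regions and
be outvoted by the agreeing medium/large scales inside their shared bands.
Fusing scales pays off in the regime the clinical work operates in —
genuinely ambiguous tissue where different receptive-field sizes make
idiosyncratic, weakly correlated mistakes — and that regime is exactly
what the synthetic generator deliberately does not emulate. The end-to-end
suite measures the fusion-versus-best-scale comparison anyway and reports
it honestly rather than restricting the fixture to boundary-free slides
where the comparison would be a trivial tie.

## Known limitations

* Dense stride-5 inference over a full-size slide is quadratic in slide
  size; the CLI and `run_infer()` expose a stride override. Strides up to
  the patch size still cover every pixel.
* The 70/30 split is at patch level within slides; overlapping patches
  share texture across the split, which is optimistic on real data. A
  slide-level split is the appropriate protocol there.
* Scale fusion assumes the three maps agree on background (true by
  construction, since the mask derives from the image).
* Training on very small patch sets is sensitive to optimization noise;
  the warmup/discriminative-rate scheme makes it dependable for the desk
  fixtures, but the validation hold-out at these sizes is only a handful of
  patches and best-epoch selection rides on it.
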