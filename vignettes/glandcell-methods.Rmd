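---
title: "Recognizing glandular epithelial cells in nucleus-centric patches: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing glandular epithelial cells in nucleus-centric patches: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Prostate adenocarcinoma arises in glandular epithelium, and quantitative
DNA-stain cytometry of individual nuclei is far more informative when each
nucleus is known to be epithelial (inside a gland) or stromal (outside).
Hand-delineating every gland in a needle biopsy is slow, and — critically —
errs in one direction: technicians reviewing a complex field miss genuinely
glandular nuclei and leave them labeled stroma, while stroma is essentially
never labeled gland. `glandcell` implements a complete workflow for learning
this gland/stroma decision per nucleus:

1. cell-centric patch extraction around segmented nucleus centers
   (`extract_patch()`, `build_biopsy_container()`),
2. an appendable per-biopsy binary container that can reconstruct the source
   image (`write_container()`, `reconstruct_image()`),
3. a VGG-lineage convolutional classifier — the GlandNet family — with a
   purpose-built C++ training engine (`glandnet()`),
4. a two-round false-positive-relabeling semi-supervised procedure that
   compensates for the one-sided annotation misses (`run_two_rounds()`),
5. an evaluation suite (eight-statistic ledger, ROC/AUC, PR/AP, four-color
   overlays, observer-consensus selection), and
6. a synthetic-tissue generator with known ground truth (`render_scene()`),
   because real annotated biopsy cohorts of this kind cannot be shared.

Nucleus segmentation itself is an upstream input (centers plus boundary
polygons), not part of this package.

## Geometry conventions

All public coordinates are 0-based `(row, col)` pairs with half-open patch
extents. A patch of even size $s$ centered on a nucleus at $(r, c)$ has its
top-left corner at $(r - s/2,\; c - s/2)$ and holds the nucleus center at
patch index $\lfloor s/2 \rfloor$ on each axis; this convention is
self-consistent across patch sizes (the same nucleus has offsets differing by
exactly $(s_2 - s_1)/2$). Patches that straddle the slide border are filled
by symmetric mirror reflection (edge pixel included) rather than a constant,
so border nuclei do not carry an artificial dark band into training.

A nucleus is *glandular* iff its center lies inside any annotated gland
polygon under the even-odd rule; centers exactly on a polygon edge count as
gland. The inclusive rule makes labels deterministic; how the original
annotation handled exactly-on-border nuclei is unknown, so this is a
documented divergence risk. Boundary-overlap voting was considered and
rejected: it needs an arbitrary area threshold and changes no label in
practice except for nuclei whose center is within a pixel of the border.

## The container format

Each biopsy is stored as one binary file: a versioned header (magic,
version, patch size, channel count, slide shape, pixel spacing, record
count, biopsy id) followed by fixed-layout records (id, slide offset, label,
optional prediction, boundary polygon in the patch frame, pixels). The byte
layout is documented in `R/cmg.R` and is normative; all integers and floats
are little-endian, pixels and polygon vertices are `float64`, so write →
read → write is byte-identical. Appending records rewrites only the header's
record count. Boundary polygons are stored once, in the patch frame; slide
coordinates are always derived as `slide_offset + vertex`.

Reconstruction places each record's pixels at its slide offset,
last-writer-wins on overlaps (neighboring nuclei overlap by construction).
Because all patches are cut from one source image, every covered pixel is
restored exactly; this is asserted in the test suite.

## GlandNet

The full-size classifier is a 16-weight-layer convolutional network in the
VGG16 lineage: thirteen 3×3 convolutions in five blocks
(64/64 – 128/128 – 256×3 – 512×3 – 512×3), 2×2 max pooling after each block,
then a head of global average pooling → dense → Gaussian noise → dense →
Gaussian noise → dense(2) → softmax — 24 layers in the enumeration that
counts convolutions, poolings, noise layers and dense layers (activations
are not counted). `glandnet_layers()` enumerates the sequence
programmatically, and the acceptance suite asserts 13 + 3 weight layers and
the 24-layer sequence.

The dense-head widths are not dictated by the lineage; defaults are 256 and
64, configurable. A `width_scale` parameter shrinks every width
proportionally for desk-scale experiments (the test suite uses 1/8 on 64-px
patches); scaled heads keep a floor of 16 units because narrower ReLU heads
can die as a whole layer, which freezes training — see *Numerical choices*.

Training minimizes the weighted categorical cross-entropy
$\mathrm{CE} = -\sum_i w_i\, y_i \log \hat y_i$ with Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$). Default class weights are inverse
class frequencies computed on the training cohort, normalized to mean 1,
countering the roughly 1:2 gland:stroma imbalance. The full-size defaults
follow the reference recipe: learning rate $10^{-5}$, batch size 128, 100
epochs, noise-layer $\sigma = 1$, final-epoch checkpoint (best-validation
checkpointing is available as a config option). A nucleus is called gland
when its predicted gland probability strictly exceeds $\tau = 0.5$; a
probability of exactly $\tau$ is stroma.

Augmentation applies horizontal/vertical flips (probability 0.5 each),
rotation up to 45°, 20% zoom and 20% shifts, in the fixed order
flip → rotate → zoom → shift, resampled bilinearly with mirror fill
(consistent with the patch-extraction padding). The rotation magnitude is
drawn uniformly from $[0, 45]$ with a random sign.

Two choices the architecture description leaves open are resolved as
follows. The tunable "noise standard deviation" is implemented as the
$\sigma$ of the head's Gaussian-noise layers (active in training only), with
`noise_on_input = TRUE` as the alternative placement. Training-history
"accuracy" is patch-level, not class-balanced. Pretrained (transfer-learned)
convolutional initialization is supported as a flag but off everywhere in
this package: tests must not require downloaded weights, so the default is
seeded He initialization.

### The training engine

No deep-learning framework is available in this package's dependency set,
and the network *is* the core method, so the engine is implemented directly
in C++ (RcppArmadillo). Activations for a mini-batch live in a zero-padded
layout in which a 3×3 convolution is nine shifted BLAS `gemm` calls over the
whole batch — no `im2col` materialization — with analytic backward passes
for convolution, max pooling, global average pooling and the dense head, and
Adam updates per tensor. The forward pass is verified in the test suite
against an independent direct-convolution reference implementation to
machine precision, and training is bit-reproducible under a fixed seed (a
dedicated Mersenne-Twister stream drives initialization, shuffling,
augmentation and the noise layers).

## Synthetic tissue

The generator emulates the few properties of Feulgen-stained prostate tissue
that the workflow actually depends on: dark ellipsoidal nuclei on a pale
background; glands as single-layer rings of roundish, radially oriented
("palisading") nuclei around an empty lumen, enclosed by a gland polygon;
stroma as sparser, strongly elongated nuclei outside all gland polygons; and
one-sided annotation misses (`inject_annotation_misses()` flips exactly
$\mathrm{round}(q \cdot n_\text{gland})$ uniformly chosen gland labels to
stroma and returns the flipped set as hidden truth). The rendered image is
background minus per-nucleus optical densities with a radial falloff,
Gaussian blur, and additive noise. Default scene parameters (384×384 canvas,
4 glands of ring radius 22–34 px with 10–16 nuclei, 120 stromal nuclei,
background 0.88, densities 0.35–0.65, blur 0.8 px, noise 0.02) give scenes of
roughly 170 nuclei at about 30% gland prevalence — matching the prevalence of
the real cohorts. Scenes are geometrically scaled down roughly fourfold
relative to 0.329 µm/px tissue so that 64-px desk-scale patches capture
whole-gland context the way 256-px patches do at full scale. A small-gland
preset (`scene_spec_small_glands()`) covers the regime where recognition
errors concentrate.

What the generator does *not* emulate: stain variability, scanner optics,
out-of-focus nuclei, nuclear texture (chromatin structure), overlapping
nuclei, and tissue-level architecture beyond single rings. Passing tests on
synthetic scenes therefore demonstrate that the *procedures* are correct
(labels, bookkeeping, recovery direction), not that the classifier reaches
any particular accuracy on real tissue.

## The two-round semi-supervised procedure

Round 1 trains on the (possibly miss-contaminated) human annotations. The
round-1 model predicts every validation nucleus; nuclei annotated stroma but
predicted gland — false positives *relative to the annotation* — are
harvested and appended to the training set as hard positives (label gland,
weight 1; a soft-label mode weighting by predicted probability exists but is
not the default). Round 2 retrains from scratch with the same initialization
scheme (warm start available as a flag). Harvesting uses the same
$\tau = 0.5$ as classification. Each round emits a ledger: class counts,
harvested ids, per-nucleus provenance (`human` vs `round-1-pseudo`, with the
human label retained immutably), and validation metrics. Conservation and
one-sidedness (the procedure can only add positives, never negatives) are
asserted as tests.

Only validation-cohort false positives are added; relabeling
training-cohort false positives in place is implemented as a clearly
non-default mode (`relabel-in-place`). The round count is fixed at 2 by
default and generalizes behind the `rounds` argument.

## Numerical choices

* **Desk-scale training recipe.** The test and demo configuration is a
  width-1/8 network on 64-px patches, learning rate 3×10⁻⁴ stepping down
  tenfold for the final third of 12 epochs, batch size 8, noise
  $\sigma = 0.15$, flips-only augmentation. These were chosen for reliable
  convergence of the *scaled* network within minutes on one CPU — the step
  decay in particular settles the output calibration around the fixed
  $\tau = 0.5$ cut, which short constant-rate runs leave unstable; the
  full-size defaults remain the reference recipe.
* **Head-width floor and bias initialization.** At width scale 1/8 the
  second dense layer would have 8 units; whole-layer ReLU death was observed
  to freeze training at a constant output. Scaled head widths therefore
  floor at 16 units and hidden dense biases initialize at +0.05.
* **Degenerate-fit restarts.** Even so, a small fraction of seeded runs
  converge to a constant predictor (every patch on one side of $\tau$).
  Such fits are detected — on the training patches in `glandnet()`, and on
  the validation predictions inside `run_two_rounds()`, where both classes
  are always present — and retried from a fresh seeded initialization (up to
  3 restarts, warning emitted, deterministic given the seed). This is the
  same convention as `nstart` in k-means or random restarts in EM: a
  degenerate optimum is a failed fit, not a result.
* **Probability clipping** at $10^{-12}$ before logarithms; softmax is
  stabilized by max subtraction.
* **Ties and degenerate metrics.** ROC sweeps move tied scores together, so
  the trapezoidal AUC equals Mann–Whitney concordance with half-weight ties
  (asserted against an $O(n^2)$ oracle). Metrics with zero denominators are
  `NA`, never 0. Cohort averages are unweighted means over biopsies, the
  convention used in the reference performance tables.
* **Cohort split rounding** uses largest remainders, so 110 biopsies at
  0.6/0.2/0.2 give exactly 66/22/22.

## Problem sizes in the test suite

The acceptance experiment for the semi-supervised property uses, per
replicate, one training scene and two validation scenes (~170 nuclei each) at
miss rates $q \in \{0.1, 0.2, 0.3\}$ with five seeded replicates per rate,
width-1/8 models and 12 epochs; the full battery takes on the order of ten
minutes on one CPU. The direction mirrors the reference observation that the
second round sharply reduces the validation false-negative rate; the
magnitudes there (13.04% → 5.76%, 21.22% → 7.57%) are cohort-specific and
are not reproduction targets.

## Known limitations

* The classifier engine is single-channel; RGB containers are collapsed to
  one channel by averaging before training.
* `checkpoint = "best_validation"` re-trains to the best epoch rather than
  snapshotting, trading time for memory.
* The synthetic generator's separability means round-1 models sometimes
  generalize past the injected label noise (near-zero hidden-truth FNR), in
  which case round 2 can only tie, not improve.
* The original study's container files are unreadable here: their byte
  layout was never published. This package's format is an independent,
  documented layout.
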