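---
title: "Weakly-supervised MIL for whole-slide carcinoma classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly-supervised MIL for whole-slide carcinoma classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(milwsi)
```

## The problem

A whole-slide image (WSI) is a gigapixel scan of a pathology slide. Tile
classifiers are the workhorse of computational pathology: the slide is cut
into fixed-size square tiles at a chosen magnification, a CNN (or any tile
scorer) assigns each tile a carcinoma probability, and the slide-level
call aggregates the tile scores. Fully supervised training of the tile
classifier needs tile labels, which in practice are derived from polygon
region annotations drawn by pathologists.

Region annotations of surgical specimens are not cell-accurate. Tumours
enclose necrotic and inflamed stroma, and pathologists outline the whole
carcinoma area rather than excluding every internal non-viable region, so
tiles cut from a "carcinoma" polygon may actually show necrosis or
inflammation — tissue that also occurs in purely non-neoplastic lesions.
Region-derived tile labels are therefore noisy in a structured way: one
appearance class (call it the *confounder*) carries the carcinoma label in
one context and the non-neoplastic label in another.

`milwsi` implements both training regimes around this problem:

* **FS (fully supervised)** — every grid tile inside an annotated region
  whose majority coverage passes a threshold is labelled by that region
  and used for training.
* **WS (weakly supervised, multiple-instance learning)** — after a short
  warm phase on randomly sampled annotated tiles, training alternates with
  inference: the frozen model scores all tissue tiles of each slide, the
  top-k tiles by carcinoma probability are selected and labelled with the
  *slide-level diagnosis*, and the model trains on them once an
  accumulation buffer fills. On a carcinoma slide the top tiles are (with
  a decent model) true carcinoma examples; on a non-neoplastic slide they
  are exactly the tiles the model most wants to call carcinoma — hard
  negatives. Over epochs this pushes the confounder's score down without
  any pixel-level annotation of where the confounder is.

Slide-level classification uses **max aggregation**: the slide probability
is the maximum over scored tiles,
$p(\text{slide}) = \max_i p(\text{tile}_i)$,
matching the MIL assumption that a positive slide contains at least one
positive tile. Evaluation is slide-level ROC AUC and log loss, with 95%
percentile-bootstrap confidence intervals over slides.

## The training protocols

Both regimes share the Adam optimiser ($\beta_1 = 0.9$,
$\beta_2 = 0.999$), batch size 64, and pixel-level augmentation (flips,
small translations with edge replication, per-channel colour shifts of
±0.04 of dynamic range, all clipped back to $[0,1]$).

**FS schedule.** Epoch 1 ramps the learning rate linearly from 0.001 to
0.05 (warm start); from epoch 2 the rate is constant within an epoch at
$0.05 \times 0.9^{(e-1)}$ — the first decay applies as epoch 1 ends, so
epoch 2 runs at 0.045. Training runs at most 22 epochs with early stopping
at patience 10 on validation loss; the returned parameters are those of
the minimum-validation-loss epoch. Validation is slide-level
(max-aggregated log loss), so FS and WS are tracked on the same scale.

**WS protocol.** A warm phase samples k = 32 labelable tiles per slide
from the annotated regions for 2 epochs (this inherits the label noise —
deliberately). MIL epochs then visit slides in seeded random order, score
all tissue tiles in inference mode, and push the top-k tiles into a
512-tile accumulation buffer labelled with the slide label; each time the
buffer fills, it is shuffled and trained in 8 batches of 64, then emptied.
k decays linearly over the MIL horizon,
$k(e) = \mathrm{round}\!\big(k_\mathrm{start} + (k_\mathrm{end} -
k_\mathrm{start}) \tfrac{e-1}{E-1}\big)$, from 5 to 1 by default. The MIL
learning rate starts at 0.001 and decays by 0.9 per epoch. The buffer
persists across epochs; a partial buffer left at the end of training is
discarded (at most one flush of data). Tie-breaks in top-k selection go to
the smaller tile index, so selection is fully deterministic.

Ranking ties in `select_top_k`, the half-up rounding in the k schedule,
and the exact flush arithmetic (`floor(selected / buffer_n)` flushes per
epoch, remainder carried) are all asserted against independent oracles in
the test suite.

## The tile classifier backbone

The backbone is pluggable behind a three-function contract
(`predict_tiles`, `train_step`, `get_params`/`set_params`). The default is
deliberately small — a desk-scale stand-in for the large CNNs used at
clinical scale: each tile is summarised by 8 colour/texture features
(per-channel mean and population sd, mean absolute luminance gradient,
mean saturation) feeding a sigmoid head trained on binary cross-entropy
with a hand-written Adam. The head is linear (logistic regression) by
default; `hidden > 0` inserts one tanh hidden layer. The loss is BCE
because slide evaluation uses log loss and the task is two-class.
`manual_classifier()` wraps any pair of functions satisfying the
contract, which the tests use for frozen scorers and instrumented
training stubs.

The linear default is a modelling choice, not a shortcut. On an 8-feature
summary of procedural textures, a wide MLP can memorise the exact mapping
from every labelled mixture level to its (noisy) region label, scoring
arbitrarily sharp steps along the tumor-purity axis; nothing like that is
possible for a CNN generalising across millions of heterogeneous real
tiles. The linear scorer's bounded-slope monotone ramp reproduces the
relevant behaviour of the clinical-scale setup: mixture tiles score
between their endmembers, so supervision quality — where the endmember
anchors are placed — is what decides slide-level accuracy.

The backbone determines what the package can and cannot learn: it sees
colour and first-order texture statistics only, so it separates the
synthetic texture classes but would not transfer to real H&E morphology.
The MIL loop itself is backbone-agnostic.

## The synthetic cohort generator

Each slide is a convex tissue blob on a near-white background, partitioned
into convex lobes (Voronoi cells of seeded points clipped to the tissue
polygon). On carcinoma slides, lobes are accumulated in random order until
a target 12–35% of the slide area is carcinoma; each selected lobe is one
carcinoma-labelled polygon annotation, and the remaining lobes are
non-neoplastic polygons, so annotations partition the tissue exactly and
the slide label follows the carcinoma-priority rule by construction.

Carcinoma polygons are not homogeneous tumor: real carcinoma annotations
enclose tumor parenchyma interspersed with stroma, fibrosis and
inflammatory infiltrate. The generator renders parenchyma as blobs of
carcinoma texture over a stromal (normal-texture) background inside each
carcinoma polygon, covering a per-slide *cellularity* fraction drawn
uniformly from 0.4–0.9. Low-cellularity slides are the hard positives —
their best tile is a parenchyma/stroma mixture rather than pure tumor —
which is what gives the cohort a realistic spread of positive-slide
scores. Without that spread, max-aggregation would hide tile-label noise
entirely: every positive slide would contain a saturating pure-tumor tile,
and the region-supervised baseline could not lose ranking accuracy no
matter how badly the confounder is scored.

Textures are procedural: a per-class mean colour plus three shared noise
terms — fine per-pixel speckle, a coarse Gaussian random field
(wavelength ~96 px, synthesised at 1/8 resolution and block-upscaled) that
moves whole-tile colour statistics, and a per-slide staining offset. All
amplitudes scale with one knob, `texture_noise_sd` (default 0.05 of
dynamic range; coarse gain 1.2, stain gain 0.6).

The confounder ("necrosis/inflammation") texture is rendered inside
carcinoma polygons until it covers `necrosis_in_carcinoma` (default 0.3)
of each polygon's area, and as patches on a `necrosis_in_negative`
(default 0.5) fraction of non-neoplastic slides — by the *same* process in
both contexts, so its pixel distribution carries no context information
(verified by a stratified two-sample KS test). Its mean colour sits close
to the carcinoma mean, at a distance comparable to the coarse-field
spread: the two tissues overlap partially in appearance. That choice is
the crux of the emulation. Necrotic and inflammatory tissue resembles
carcinoma stroma; if the confounder were trivially distinguishable from
carcinoma, a region-supervised learner would simply learn both classes
separately and max-aggregation would mask the label noise entirely, while
full inseparability would cap both regimes at the same Bayes error. The
partial-overlap regime is where supervision quality matters: FS anchors
the confounder at a high probability (it mostly sees it labelled
carcinoma), while the WS hard-negative stream concentrates exactly on
those tiles and pushes them down.

What the generator does *not* emulate: real H&E morphology (nuclei,
glands), stain deconvolution-level colour physics, scanner artefacts,
pyramid levels, or annotation disagreement between pathologists. Passing
tests on synthetic cohorts therefore demonstrates the training loop's
mechanics and the supervision comparison — not clinical performance.

## Desk-scale protocol

The reference constants (512-px tiles, stride 256 at ×10, buffer 512,
~10^6 iterations) assume thousands of gigapixel slides and a large CNN.
The package keeps those as configuration defaults and provides a frozen
desk-scale protocol (`desk_cohort_spec()`, `desk_fs_config()`,
`desk_mil_config()`, `desk_compare_regimes()`) used by the examples and
the acceptance script: 120 slides of 512×512 px per cohort (64 train / 16
validation / 40 held out), 64-px tiles, training grid stride 64, inference
stride 32. FS runs 10 epochs of the reference schedule. The MIL phase
keeps the warm phase (k = 32, 2 epochs) and the linear top-k decay but
spreads it over 15 epochs with a 64-tile buffer and a starting rate of
0.05 decaying by 0.95 — with 64 training slides and k ≤ 5 the selection
stream is roughly two orders of magnitude smaller than at clinical scale,
and these settings restore a comparable number of parameter updates
relative to model size. Validation scoring inside training uses stride =
tile size for speed; held-out scoring uses the half-tile stride of the
reference protocol.

## Numerical and design choices

* Coordinates are 0-based, x = column / y = row, half-open tile windows,
  everything at working magnification; right/bottom margins that do not
  fit a full tile are dropped (max aggregation is insensitive to a thin
  margin).
* Magnification downsampling is area (block-mean) averaging; only integer
  base/working ratios are supported (the reference use is ×20 → ×10).
* The tissue mask calls a pixel background when its HSV value exceeds 0.90
  at saturation below 0.12; tiles enter training or scoring only if at
  least 10% tissue (configurable). Without a filter, background tiles
  dominate the MIL buffer.
* Tile labels use majority region coverage with `min_overlap` 0.5 and ties
  toward carcinoma; coverage is exact polygon–rectangle clipping
  (Sutherland–Hodgman; generator polygons are convex), tested against a
  rasterised pixel-count oracle. Same-class regions are assumed disjoint.
* Carcinoma slide count in a cohort is `floor(n × fraction + 0.5)` (round
  half up), assigned to the first indices of a seeded shuffle.
* The bootstrap resamples slides (never tiles) with replacement, 1000
  iterations, percentile interval at 95%; single-class resamples are
  redrawn with a global cap of 10 × iterations. Log-loss probabilities
  are clipped at 10⁻¹⁵.
* All randomness flows from one master seed through named substreams
  (`substream_seed`), so each stage is reproducible in isolation and the
  full pipeline is byte-deterministic.

## Limitations

The desk-scale backbone cannot represent morphology, only colour/texture
summaries; conclusions about real WSI cohorts require swapping in a CNN
backbone and a pyramidal slide reader, both of which sit behind existing
contracts (`TileClassifier`, `load_slide`). Early stopping in WS mode
validates per MIL epoch (whether that matches the reference protocol's
epoch accounting is not determinable from its description). The MIL phase
uses slide labels only after the warm phase; annotations are never
consulted again. No significance test between the two regimes is
implemented — only paired AUC comparison on shared seeds — because no such
test is specified for the reference results.
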