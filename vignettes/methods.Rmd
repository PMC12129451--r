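---
title: "Micronucleus segmentation in mnseg: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micronucleus segmentation in mnseg: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnseg)
```

## The problem

Micronuclei (MN) are small chromatin-containing compartments that form
outside the primary nucleus after chromosome missegregation or DNA damage.
Segmenting them in fluorescence images of chromatin-labeled cells is hard for
classical thresholding because MN span a ten-fold size range (1--10 µm
diameter), sit very close to the nucleus, share the nucleus' chromatin
texture and intensity, and are easily confused with nuclear blebs, chromatin
bridges and debris. A further biological readout -- whether a given MN has
lost nuclear-envelope integrity ("ruptured") -- is visible as loss of a
nuclear-localized reporter (an NLS-tagged fluorophore) from the MN while the
nucleus stays bright.

`mnseg` implements two complementary pipelines:

* **The rapid crop pipeline** (`vcs_classify_field()`): segment nuclei,
  cut a fixed-size crop around each nucleus, predict MN pixels within the
  crop, map them back to the field, assign each MN to its nearest nucleus,
  and call rupture from the reporter ratio. It is designed for
  on-microscope use, where nucleus-level MN+/MN− and rupture+/rupture−
  calls drive photoconversion-based cell sorting, so speed and nucleus-level
  accuracy matter more than pixel-perfect masks.
* **The tiled ensemble pipeline** (`mnfinder_segment()`): slide a
  128×128 px window with 96 px stride over the field, classify every tile
  with an ensemble of attention-gated U-Nets plus a consensus net, predict
  cell-instance gradient maps with a three-decoder network, post-process
  (small-nucleus reclassification, convex-hull MN expansion, seeded
  watershed with oversegmentation repair), and integrate results into final
  nucleus / MN / cell labels with associations.

## Pipeline constants

All decision constants live in `mn_config()` and are applied at the working
(rescaled) resolution, not the acquisition resolution, so pixel-denominated
thresholds are resolution-stable:

| parameter | default | units | role |
|---|---|---|---|
| `rupture_ratio_threshold` | 0.16 | intensity ratio | MN with max reporter intensity strictly below this fraction of the nucleus max are ruptured |
| `nucleus_min_area` | 250 | px | nucleus components strictly below this area are reclassified as MN |
| `mn_discard_radius` | 40 | px | MN strictly farther than this from every nucleus are discarded |
| `working_resolution_range` | 1.55--2.8 | px/µm | images outside are linearly rescaled in |
| `tile_size`, `tile_stride` | 128, 96 | px | sliding-window tiling (oversampled: 32 px overlap) |
| `vcs_crop_size`, `vcs_net_input_size` | 48, 96 | px | nucleus crop and its enlarged network input |
| `split_fractions` | 0.65/0.07/0.28 | -- | train/validation/test split at the field level |

Strictness follows the natural-language reading of each rule: rupture if
ratio `<` 0.16, reclassify if area `<` 250, discard if distance `>` 40.
The boundary probes in `scripts/acceptance.R` recompute all three decision
boundaries from the installed package's behavior.

Distance in the assignment rule is mask-to-mask (minimum Euclidean distance
between pixel centers of the two objects), not centroid-to-centroid, because
MN sizes vary ten-fold and a centroid rule would make the 40 px cut depend
on object size. MN lying entirely inside a nucleus mask are discarded as
false signals.

## The synthetic-data generator

Real training corpora for this problem are annotated microscope images that
cannot ship with a package. `generate_field()` draws two-channel fields with
exact ground truth so that every algorithmic stage is testable end to end:

* **Nuclei**: ellipses with semi-axes 12--17 × 10--14 px (about 30 px
  diameter at the default 2 px/µm), with a low-frequency sinusoidal boundary
  perturbation emulating lobulated nuclei, the main false-positive source in
  real data.
* **MN**: lognormal pixel areas with median 34 px (clamped to 6--150 px,
  covering the 1--10 µm diameter range at working resolution), placed at
  2--10 px gaps from the parent boundary. Placement retries until the
  nearest other nucleus is at least `parent_proximity_factor` (3.3) times
  farther than the parent, so the nearest-nucleus assignment heuristic is
  right by construction but not trivially so.
* **Rupture contrast**: intact MN carry 30--90 % of their nucleus' reporter
  amplitude, ruptured MN 0.5--5 %. With the default background (0.02) and
  read noise (sd 0.005) both classes sit far from the 0.16 ratio on the
  correct side; the generator is calibrated for raw-intensity ratios with no
  background subtraction, matching the classifier's definition.
* **Distractors**: nuclear blebs (protrusions contiguous with the nucleus),
  chromatin bridges (thin curves connecting two nuclei, assigned to the
  nearer nucleus), and dim debris. Blebs and bridges are nucleus-class
  pixels; debris is intensity-only and appears in no mask. None of them ever
  enters the MN ground truth.
* **Rendering**: per-object amplitude jitter, a σ = 0.5 px Gaussian optical
  blur, uniform background, Gaussian read noise. Intensities are arbitrary
  units; every pipeline threshold is ratio- or size-based, never absolute.

What the generator does *not* emulate: realistic point-spread functions,
focus drift, uneven illumination, chromatin texture, touching/overlapping
nuclei at high confluency, and 3D structure. Passing tests on synthetic
fields therefore demonstrate algorithmic correctness of the pipeline stages,
not expected performance on real microscope images.

Training sets are split at the field level (floor for train and validation
counts, remainder to test) so no field leaks across splits; augmentation
(90° rotations and flips) is applied only to the training split.

## Neural networks

No deep-learning framework is available to this package, so it ships a
compact reverse-mode automatic-differentiation engine (`R/nn-core.R`):
tensors are `(H, W, C, N)` arrays, convolutions are im2col gathers feeding
BLAS matrix products, and every operator carries an analytic backward
closure. Gradients are verified against central finite differences in the
test suite to ~1e-9 relative error.

**Nuc/MN pixel classifier.** Two attention-gated U-Nets (encoder depth 4;
attention gates on every decoder skip; softmax over background / nucleus /
MN), one of which adds multiscale downsample blocks that pool the raw input
to each encoder scale and inject it through a 1×1 convolution. Their
MN-probability maps are stacked and fed to a third, consensus U-Net; the
final MN map comes from the consensus net while background/nucleus maps come
from the plain U-Net (renormalized per pixel). The consensus net is trained
with the input nets frozen. Training minimizes the focal loss (default
γ = 2, α = inverse class frequency) because MN occupy well under 1 % of
pixels. γ = 0 reduces exactly to weighted cross-entropy, which the tests
assert.

**Cell-instance network.** A shared encoder with three decoders: a
foreground decoder with plain addition-merged skips, and distance /
proximity decoders with full-scale skip connections (every encoder level and
every coarser decoder level resampled to the current scale, projected 1×1
and added) that also receive the foreground decoder's features. The
distance and proximity pathways carry one deep-supervision head per decoder
scale, all trained with equal-weight mean-squared error.

Architectural simplifications relative to common practice: upsampling is
nearest-neighbour and there are no normalization layers. Both keep the
hand-written backward passes simple and exact, and at the tiny widths this
package trains (base width 4--32) they did not prevent the desk-scale
training checks from passing. He-normal initialization, Adam, seeded
shuffling; runs are deterministic on a single thread.

**Oracle backends.** Every model slot accepts a ground-truth-backed oracle
(`oracle_pixel_model()`, `oracle_map_model()`, `oracle_vcs_model()`) that
emits perfect (optionally blurred) predictions. Oracles make the
post-processing chain testable in isolation: with oracle inputs, the full
tiled pipeline must recover every MN exactly, and the test suite asserts
recall = PPV = 1 with per-object mIoU ≥ 0.95 over 20 generated fields.

## Ground-truth maps

A "cell" is the smallest convex shape enclosing a nucleus and its MN.
From the cell hulls three maps are built, each zero outside every hull and
max-normalized to 1 per cell:

* **foreground**: 1 inside any hull;
* **distance**: exact Euclidean distance to the nearest non-hull pixel;
* **proximity**: exact Euclidean distance to the nearest pixel of any
  *other* hull, masked to the cell, raised to the 4th power to sharpen the
  falloff at cell-cell interfaces, then normalized. An isolated cell has no
  other-hull pixels; its distances are capped at the field diagonal, which
  normalizes to a constant 1.

The EDT is a Felzenszwalb--Huttenlocher separable transform written in R
(exact squared distances; the row pass can be restricted to a bounding band,
so per-cell maps pay only for their bounding box). EBImage's distance map
was not used because the acceptance suite requires bit-exact agreement with
a brute-force O(N²) reference, which the tests check on hundreds of random
fixtures.

Two rasterization conventions worth noting: a pixel belongs to a convex hull
iff its center is inside or on the hull polygon (integer cross-product test,
exact); when two cells' hulls claim the same pixel, the pixel goes to the
cell with the nearer nucleus centroid (ties to the lower id), so hull masks
partition the foreground and per-cell normalization is well defined. The
Methods-style concave grouping is available as `mode = "concave"`
(morphological closing with a disc of radius `concavity`, then hole
filling); the convex mode is the default and the tested mode.

## Watershed post-processing and its repair rule

Cell objects are recovered by summing the distance and proximity maps,
thresholding the sum (default 0.5) for seeds, and growing seeds over the
foreground on the inverted sum (EBImage's `propagate`). Because seeds can
split one true cell, a repair step follows. The published description keeps
boundary pixels that "touch background or the skeletonized proximity map";
making that operational required two decisions:

* **Which structure to skeletonize.** At a true cell-cell interface the
  per-cell proximity map falls to ~0 on both sides (the 4th power drives it
  down fast), so the interface is a deep, narrow valley. We therefore
  skeletonize the *low*-proximity band (foreground with proximity below
  `proximity_skeleton_threshold`, default 0.5): its medial line traces the
  interface. Skeletonizing the high-proximity region instead would put the
  skeleton through every cell's interior, where it would validate exactly
  the false splits the step is meant to remove -- including the canonical
  fixture of a uniform-proximity cell split by two seeds, which must merge.
* **Aggregation.** A boundary's endpoints always touch background where it
  meets the object rim, so "any supported pixel" would keep every boundary.
  A boundary therefore survives only if at least *half* of its pixels touch
  background or the skeleton (8-connectivity, one-pixel tolerance);
  otherwise the two objects merge.

Finally, watershed objects smaller than `nucleus_min_area` are absorbed into
the neighbor with the longest shared boundary: a cell must at minimum be
able to contain a nucleus, and such slivers are always seed artifacts.

Label integration then assigns each MN to the nucleus sharing its cell
object -- cell membership deliberately overrides raw distance, because the
instance branch exists precisely to fix proximity errors -- with
nearest-nucleus assignment within `mn_discard_radius` as the fallback for MN
outside all cells, and dropping as the last resort.

## Evaluation definitions

A single pixel of overlap suffices to match objects: a true MN is recalled
iff any predicted object overlaps it, and a predicted object is a true
positive iff it overlaps any true MN (many-to-one allowed both ways).
Per-object mIoU averages, over *matched* ground-truth objects only, the IoU
between the true pixel set and the union of its matched predictions;
unmatched objects affect recall, not mIoU. Nucleus-level metrics are
per-class recall/PPV from the MN+/MN− confusion table and, among MN+ nuclei,
the rupture+/rupture− table.

The sorted-population model treats classifier errors and sorter errors as
independent: a population with MN+ frequency *f* is split by per-class
recalls into TP/FN/TN/FP mass, each sorting bin receives `sort_accuracy` of
its intended pool and the complement of the other, and purity / enrichment
follow in closed form. The rupture-drift adjustment multiplies a PPV by
(1 − *d*) for a drift fraction *d* (intact MN that rupture during the
experiment convert true positives into false positives). Both models are
checked against Monte-Carlo simulation and closed-form limits in the tests.

## Problem sizes used by the test and acceptance suites

The suites run entirely on generated data with fixed seeds: 20 fields of
256×256 px with 8 cells each for the end-to-end oracle property; 100 random
fixtures up to 64×64 px per geometric primitive for the brute-force
equivalence checks; 500 simulated reporter ratios for threshold recovery;
and, for the trainability checks, a base-width-8 classifier trained 20
epochs on 200 foreground-enriched 32×32 crops (and a base-width-8 cell net
for 6 epochs on 80 crops). These sizes were chosen as the smallest at which
each property is cleanly expressed; all of them are parameters, and larger
runs only sharpen the same checks.

## Known limitations

* Synthetic fields are far cleaner than microscope data; trained-from-
  scratch performance on real images is out of scope here and would require
  the original annotated corpora.
* The crop pipeline can miss MN that protrude beyond the fixed 48 px window
  of a large or distant parent nucleus -- the same far-MN failure mode
  reported for the original rapid classifier.
* The pure-R training loop is desk-scale: minutes for tiny widths on small
  crops; it is a faithful, testable implementation of the architectures,
  not a performance platform.
* 2D only; no time-lapse tracking; chromatin bridges are labeled
  nucleus-class and bridge-mediated nucleus merges are resolved only by the
  cell-instance branch.
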