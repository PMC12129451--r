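# mnseg

Segmentation and classification of micronuclei (MN) in 2D fluorescence
microscopy images of chromatin-labeled cells, with reporter-based
classification of MN nuclear-envelope rupture.

Micronuclei — small chromatin compartments formed outside the primary
nucleus after chromosome missegregation — are hard to segment: they span a
ten-fold size range (1–10 µm diameter), hug the nucleus, match its chromatin
intensity, and are easily confused with nuclear blebs, chromatin bridges and
debris. `mnseg` is for cell biologists and image analysts who need per-cell
MN counts, MN–nucleus associations, and intact/ruptured calls, either
on-microscope (to drive photoconversion-based visual cell sorting) or
offline at higher accuracy.

The package implements two pipelines:

* **Rapid crop pipeline** (`vcs_classify_field()`) — segment nuclei (Otsu +
  watershed built-in, or any injected segmenter), cut a 48×48 px crop around
  each nucleus, predict MN pixels at 96×96 with a three-channel (chromatin,
  duplicate, Sobel) network, map predictions back, assign each MN to the
  nearest nucleus (mask-to-mask distance ≤ 40 px, else discard), and call
  rupture by the reporter ratio rule: an MN is **ruptured** iff

  `max reporter intensity over MN pixels / max over nucleus pixels < 0.16`.

  Nuclei become MN+ / MN− and, among MN+, rupture+ (≥ 1 ruptured MN) /
  rupture− (all intact).

* **Tiled ensemble pipeline** (`mnfinder_segment()`) — rescale into the
  1.55–2.8 px/µm working range, tile with a 128×128 px window at 96 px
  stride, classify pixels with an ensemble of attention-gated U-Nets (plain
  + multiscale encoder, MN maps fused by a consensus U-Net, focal loss), and
  in parallel predict per-cell **distance** and **proximity** maps (exact
  EDTs of the convex "cell" hull of nucleus + MN, proximity raised to the
  4th power, both 0–1 per cell) with a three-decoder UNet3+-style network.
  Post-processing reclassifies nucleus components under 250 px as MN,
  expands MN to their convex hulls, runs seeded watershed on the summed
  maps with an interface-skeleton repair rule, and integrates everything
  into nucleus / MN / cell labels with associations; tiles are reassembled
  by linear blending.

Both network families run on a small pure-R reverse-mode autodiff engine
included in the package (BLAS-backed im2col convolutions, finite-difference
verified gradients), and every model slot also accepts a ground-truth
*oracle* backend, which makes the entire post-processing chain testable
without trained weights. A synthetic two-channel field generator with exact
ground truth (`generate_field()`), object-level metrics (recall, PPV,
per-object mIoU under the single-pixel-overlap rule), and closed-form
sorted-population purity/enrichment models round out the toolkit.

## Worked example

```r
library(mnseg)

f <- generate_field(synth_config(seed = 42))
f$image
#> <field_image> 256x256 px, 2 px/um, channels: chromatin, reporter
f$gt
#> <ground_truth> 8 nuclei, 7 MN (4 ruptured)

seg <- mnfinder_segment(f$image, oracle_pixel_model(f$gt), oracle_map_model(f$gt))
seg
#> <mn_segmentation> 7 nuclei, 7 MN (0 dropped), 8 cells
head(seg$assignments)
#>   mn_id nucleus_id  distance ruptured
#> 1     1          2 10.440307    FALSE
#> 2     2          1  8.544004     TRUE
#> 3     3          2  5.830952    FALSE
#> 4     4          3  7.615773     TRUE
#> 5     5          6 10.000000     TRUE
#> 6     6          6 10.295630     TRUE

ev <- evaluate_mn_segmentation(seg$mn_mask, f$gt)
sprintf("recall %.2f  PPV %.2f  per-object mIoU %.3f", ev$recall, ev$ppv, ev$miou)
#> "recall 1.00  PPV 1.00  per-object mIoU 1.000"
```

Every MN was recovered (recall 1), nothing spurious was called (PPV 1), and
the recovered pixel masks match the ground truth exactly (mIoU 1); each
`assignments` row links one MN to its parent nucleus with the mask-to-mask
distance in pixels and its rupture call. (This field reports 7 nuclei for 8
ground-truth nuclei because a chromatin bridge fuses two of them into one
nucleus-class component — a known property of pixel-class segmentation that
the cell-instance branch compensates for during association.)

The sorting model predicts what a photoconversion + FACS experiment would
recover from a low-MN-frequency population:

```r
m <- sorted_population_model(f = 0.078, recall_pos = 0.83, recall_neg = 0.82,
                             sort_accuracy = 0.95)
sprintf("MN+ bin purity %.3f  enrichment %.2f-fold", m$purity_pos, m$enrichment)
#> "MN+ bin purity 0.241  enrichment 3.09-fold"
```

At a starting MN+ frequency of 7.8 %, the sorted MN+ bin is 24 % micro-
nucleated — a 3-fold enrichment under these classifier/sorter settings.

See `vignettes/methods.Rmd` for the models, parameters, numerical choices
and limitations.

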