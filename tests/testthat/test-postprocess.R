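test_that("nucleus components below 250 px become MN, 250 px stays nucleus", {
  cfg <- mn_config()
  mk <- function(area) {
    side <- floor(sqrt(area))
    nuc <- matrix(0L, 64, 64)
    nuc[10 + seq_len(side), 10 + seq_len(side)] <- 1L
    extra <- area - side^2
    if (extra > 0) nuc[10 + side + 1L, 10 + seq_len(extra)] <- 1L
    nuc
  }
  for (area in c(249L, 250L)) {
    nuc <- mk(area)
    out <- reclassify_small_nuclei(nuc, matrix(0L, 64, 64), cfg)
    if (area < 250) {
      expect_length(mask_labels(out$nucleus_mask), 0L)
      expect_length(mask_labels(out$mn_mask), 1L)
    } else {
      expect_length(mask_labels(out$nucleus_mask), 1L)
      expect_length(mask_labels(out$mn_mask), 0L)
    }
  }
})

test_that("exactly the sub-threshold components are reclassified", {
  cfg <- mn_config()
  nuc <- matrix(0L, 120, 120)
  nuc[2:11, 2:11] <- 1L       # 100 px -> MN
  nuc[20:49, 20:39] <- 2L     # 600 px -> stays
  nuc[60:89, 60:89] <- 3L     # 900 px -> stays
  out <- reclassify_small_nuclei(nuc, matrix(0L, 120, 120), cfg)
  expect_length(mask_labels(out$nucleus_mask), 2L)
  expect_length(mask_labels(out$mn_mask), 1L)
  expect_equal(sum(out$mn_mask > 0), 100L)
  # conservation: no foreground pixel lost
  expect_equal(sum(out$nucleus_mask > 0) + sum(out$mn_mask > 0), sum(nuc > 0))
})

test_that("hull expansion fixes concave MN, leaves convex ones, and never eats neighbors", {
  mn <- draw_disc(matrix(0L, 64, 64), 20, 20, 5, 1L)
  expect_identical(expand_mn_to_hull(mn), mn)  # a disk is its own hull
  # C shape: output equals the brute-force hull; area strictly increases
  cmask <- matrix(0L, 64, 64)
  cmask[20:30, 20:22] <- 1L
  cmask[20:22, 20:30] <- 1L
  cmask[28:30, 20:30] <- 1L
  out <- expand_mn_to_hull(cmask)
  expect_setequal(which(out > 0), which(bf_hull_mask(cmask)))
  expect_gt(sum(out > 0), sum(cmask > 0))
  # overlapping expansions are adjudicated by nearest original centroid
  two <- matrix(0L, 40, 40)
  two[10:20, 8:10] <- 1L; two[10:12, 8:18] <- 1L    # L-shape, label 1
  two[10:20, 22:24] <- 2L; two[10:12, 14:24] <- 2L  # mirrored, overlapping hulls
  two[two == 2L & ((two * 0 + col(two)) < 14)] <- 2L
  res <- expand_mn_to_hull(two)
  expect_true(all(res[two > 0] == two[two > 0]))  # originals never relabeled
  expect_setequal(mask_labels(res), c(1L, 2L))
  # idempotence: expanding an expansion changes nothing
  expect_identical(expand_mn_to_hull(res), res)
  # never overwrites nucleus pixels (nucleus sits inside the C's cavity)
  nuc <- matrix(0L, 64, 64); nuc[24:26, 24:26] <- 1L
  out2 <- expand_mn_to_hull(cmask, nuc)
  expect_equal(sum(out2 > 0 & nuc > 0), 0L)
})

test_that("watershed cell segmentation recovers isolated and adjacent cells", {
  cfg <- mn_config()
  # single cell: one object covering the hull
  nuc <- draw_disc(matrix(0L, 64, 64), 32, 32, 10, 1L)
  gt <- make_gt(nuc, matrix(0L, 64, 64), integer(0))
  hulls <- make_cell_hulls(gt)
  maps <- make_map_set(hulls)
  cells <- segment_cells(maps, cfg)
  expect_length(mask_labels(cells), 1L)
  hull_px <- hulls$cells[[1]]$idx
  jac <- length(intersect(which(cells == 1), hull_px)) /
    length(union(which(cells == 1), hull_px))
  expect_gte(jac, 0.99)
  # two well-separated cells stay two objects
  nuc2 <- draw_disc(matrix(0L, 96, 96), 25, 25, 9, 1L)
  nuc2 <- draw_disc(nuc2, 70, 70, 9, 2L)
  gt2 <- make_gt(nuc2, matrix(0L, 96, 96), integer(0))
  maps2 <- make_map_set(make_cell_hulls(gt2))
  expect_length(mask_labels(segment_cells(maps2, cfg)), 2L)
  # empty foreground: empty mask, no error
  empty <- structure(list(foreground = matrix(0, 32, 32),
                          distance = matrix(0, 32, 32),
                          proximity = matrix(0, 32, 32)),
                     class = "mn_map_set")
  expect_equal(max(segment_cells(empty, cfg)), 0L)
})

test_that("a seed-split cell without a proximity ridge is merged back to one", {
  cfg <- mn_config()
  # one isolated square cell; the predicted proximity is flat (no ridge, as
  # for a cell without neighbors) and the distance map dips below the seed
  # threshold along the middle, forcing two watershed seeds in one true cell
  fg <- matrix(0, 64, 64)
  fg[20:45, 16:49] <- 1
  dist <- matrix(0, 64, 64)
  for (c2 in 16:49) dist[20:45, c2] <- pmin(c2 - 15, 50 - c2) / 17
  dist[, 31:34] <- 0  # artificial valley, no proximity support
  dist[fg == 0] <- 0
  prox <- 0.3 * fg  # flat imperfect prediction: no interface structure
  maps <- structure(list(foreground = fg, distance = dist, proximity = prox),
                    class = "mn_map_set")
  seeds <- (dist + prox) > cfg$cell_seed_threshold & fg > 0.5
  expect_gt(max(label_components(seeds)), 1L)  # the fixture really splits
  cells <- segment_cells(maps, cfg)
  expect_length(mask_labels(cells), 1L)
})

test_that("integration assigns by shared cell first, then proximity, then drops", {
  cfg <- mn_config()
  f <- generate_field(synth_config(seed = 2))
  seg <- mnfinder_segment(f$image, oracle_pixel_model(f$gt), oracle_map_model(f$gt))
  # every MN got the ground-truth parent (mapped through overlap)
  m <- match_objects(seg$mn_mask, f$gt$mn_mask)
  for (r in seq_len(nrow(m$pairs))) {
    pid <- m$pairs$pred_id[r]; gid <- m$pairs$gt_id[r]
    pred_parent <- seg$assignments$nucleus_id[match(pid, seg$assignments$mn_id)]
    gt_parent <- f$gt$mn_parent[[as.character(gid)]]
    ov <- table(seg$nucleus_mask[f$gt$nucleus_mask == gt_parent])
    ov <- ov[names(ov) != "0"]
    expect_equal(as.integer(names(which.max(ov))), pred_parent)
  }
  # an MN inside its own cell is assigned there even when another nucleus is
  # closer by raw distance
  nuc <- matrix(0L, 100, 100)
  nuc <- draw_disc(nuc, 30, 30, 10, 1L)
  nuc <- draw_disc(nuc, 30, 62, 10, 2L)
  mn <- draw_disc(matrix(0L, 100, 100), 30, 47, 3, 1L)  # nearer to nucleus 2
  cells <- matrix(0L, 100, 100)
  cells[10:50, 10:50] <- 1L   # cell of nucleus 1 includes the MN
  cells[10:50, 52:90] <- 2L
  res <- integrate_results(nuc, mn, cells, config = cfg)
  expect_equal(res$assignments$nucleus_id, 1L)
  # empty MN mask: zero assignment rows, all nuclei MN-
  res2 <- integrate_results(nuc, matrix(0L, 100, 100), cells, config = cfg)
  expect_equal(nrow(res2$assignments), 0L)
  expect_true(all(res2$labels$mn_status == "MN-"))
  # with no nuclei at all, MN are dropped with a warning
  expect_warning(
    res3 <- integrate_results(matrix(0L, 100, 100), mn, cells, config = cfg),
    "dropping")
  expect_length(mask_labels(res3$mn_mask), 0L)
})

test_that("object tables report area, intensity, solidity and row counts", {
  img <- field_image(list(chromatin = matrix(100, 32, 32)), 2)
  mask <- matrix(0L, 32, 32)
  mask[5:8, 5:9] <- 1L  # 4x5 rectangle, 20 px, convex
  tab <- measure_objects(list(mn = mask), image = img)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$area, 20L)
  expect_equal(tab$mean_chromatin, 100)
  expect_equal(tab$max_chromatin, 100)
  expect_equal(tab$solidity, 1.0)
  mask2 <- draw_disc(mask, 20, 20, 4, 2L)
  tab2 <- measure_objects(list(mn = mask2))
  expect_equal(nrow(tab2), length(mask_labels(mask2)))
})

test_that("postprocessing is idempotent on its own output", {
  cfg <- mn_config()
  f <- generate_field(synth_config(seed = 14))
  seg <- mnfinder_segment(f$image, oracle_pixel_model(f$gt), oracle_map_model(f$gt))
  again <- reclassify_small_nuclei(seg$nucleus_mask, seg$mn_mask, cfg)
  expect_equal(sum(again$nucleus_mask > 0), sum(seg$nucleus_mask > 0))
  expect_equal(sum(again$mn_mask > 0), sum(seg$mn_mask > 0))
  expect_identical(expand_mn_to_hull(seg$mn_mask, seg$nucleus_mask), seg$mn_mask)
})
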