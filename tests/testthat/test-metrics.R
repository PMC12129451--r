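test_that("single-pixel overlap suffices for detection matching", {
  gt <- draw_disc(matrix(0L, 32, 32), 10, 10, 4, 1L)
  expect_equal(match_objects(gt, gt)$recall, 1.0)
  expect_equal(match_objects(gt, gt)$ppv, 1.0)
  # prediction overlapping by exactly one pixel still recalls the object
  pred <- matrix(0L, 32, 32)
  touch <- which(gt > 0)[1]
  pred[touch] <- 1L
  pred[25, 25] <- 0L
  m <- match_objects(pred, gt)
  expect_equal(m$recall, 1.0)
  expect_equal(m$tp, 1L)
  # a disjoint prediction is a false positive; a missed object a false negative
  pred2 <- draw_disc(matrix(0L, 32, 32), 25, 25, 2, 1L)
  m2 <- match_objects(pred2, gt)
  expect_equal(m2$fp, 1L)
  expect_equal(m2$fn, 1L)
  expect_equal(m2$recall, 0)
  expect_equal(m2$ppv, 0)
})

test_that("matching counts equal brute-force overlap enumeration", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(c(24, 32), 1)
    gt <- random_blob_mask(n, sample(2:4, 1), rmin = 2, rmax = 5)
    pred <- random_blob_mask(n, sample(2:4, 1), rmin = 2, rmax = 5)
    m <- match_objects(pred, gt)
    b <- bf_match(pred, gt)
    expect_equal(m$tp, b$tp)
    expect_equal(m$fp, b$fp)
    expect_equal(m$fn, b$fn)
    expect_equal(m$recall, b$recall)
    expect_equal(m$ppv, b$ppv)
    # symmetry: swapping prediction and truth swaps recall and PPV
    ms <- match_objects(gt, pred)
    expect_equal(ms$recall, m$ppv)
    expect_equal(ms$ppv, m$recall)
  }
})

test_that("per-object mIoU: exact masks, 2x dilation, and brute-force equality", {
  gt <- draw_disc(matrix(0L, 40, 40), 20, 20, 5, 1L)
  expect_equal(per_object_miou(gt, gt), 1.0)
  # containment at exactly twice the area gives IoU 0.5
  area <- sum(gt > 0)
  pred <- gt
  grow <- which(mnseg:::.touches(gt > 0) & gt == 0)
  pred[grow[seq_len(min(area, length(grow)))]] <- 1L
  while (sum(pred > 0) < 2 * area) {
    grow <- which(mnseg:::.touches(pred > 0) & pred == 0)
    need <- 2 * area - sum(pred > 0)
    pred[grow[seq_len(min(need, length(grow)))]] <- 1L
  }
  expect_equal(per_object_miou(pred, gt), 0.5)
  # random fixtures against direct per-object computation
  set.seed(29)
  for (rep in 1:5) {
    gt2 <- random_blob_mask(32, 3, rmin = 2, rmax = 5)
    pred2 <- random_blob_mask(32, 3, rmin = 2, rmax = 5)
    m <- match_objects(pred2, gt2)
    if (nrow(m$pairs) == 0) {
      expect_true(is.na(per_object_miou(pred2, gt2, m)))
      next
    }
    ious <- c()
    for (g in unique(m$pairs$gt_id)) {
      preds <- m$pairs$pred_id[m$pairs$gt_id == g]
      gpx <- which(gt2 == g)
      ppx <- which(matrix(pred2 %in% preds, 32))
      ious <- c(ious, length(intersect(gpx, ppx)) / length(union(gpx, ppx)))
    }
    expect_equal(per_object_miou(pred2, gt2, m), mean(ious))
  }
})

test_that("nucleus classification metrics reduce to the confusion table", {
  truth <- nucleus_labels(1:6,
                          c("MN+", "MN+", "MN+", "MN-", "MN-", "MN-"),
                          c("rupture+", "rupture-", "rupture-", NA, NA, NA),
                          list(1L, 2L, 3L, integer(0), integer(0), integer(0)))
  perfect <- nucleus_classification_metrics(truth, truth)
  expect_equal(perfect$`MN+`$recall, 1.0)
  expect_equal(perfect$`MN-`$ppv, 1.0)
  expect_equal(perfect$`rupture+`$recall, 1.0)
  # degenerate classifier: everything MN+
  allpos <- nucleus_labels(1:6, rep("MN+", 6), rep("rupture-", 6),
                           as.list(rep(1L, 6)))
  m <- nucleus_classification_metrics(allpos, truth)
  expect_equal(m$`MN+`$recall, 1.0)
  expect_equal(m$`MN+`$ppv, 0.5)  # true MN+ frequency
  # hand-computed mixed case
  pred <- nucleus_labels(1:6,
                         c("MN+", "MN-", "MN+", "MN+", "MN-", "MN-"),
                         c("rupture-", NA, "rupture-", "rupture-", NA, NA),
                         list(9L, integer(0), 9L, 9L, integer(0), integer(0)))
  m2 <- nucleus_classification_metrics(pred, truth)
  expect_equal(m2$`MN+`$recall, 2 / 3)
  expect_equal(m2$`MN+`$ppv, 2 / 3)
  expect_equal(m2$`MN-`$recall, 2 / 3)
  expect_error(nucleus_classification_metrics(truth[1:5, ], truth), "same nucleus")
})

test_that("mn_frequency is the MN+ share of nuclei", {
  lab <- nucleus_labels(1:4, c("MN+", "MN+", "MN+", "MN+"),
                        rep("rupture-", 4), as.list(1:4))
  expect_equal(mn_frequency(lab), 1.0)
  mixed <- nucleus_labels(1:1000,
                          rep(c("MN+", "MN-"), c(78, 922)),
                          c(rep("rupture-", 78), rep(NA, 922)),
                          c(as.list(1:78), rep(list(integer(0)), 922)))
  expect_equal(mn_frequency(mixed), 0.078)
})

test_that("generator frequency is recovered within binomial error", {
  labels <- c()
  for (s in 1:6) {
    f <- generate_field(synth_config(seed = s, mn_frequency = 0.5,
                                     field_size = 320L, n_cells = 12L))
    gt <- f$gt
    has <- mask_labels(gt$nucleus_mask) %in% gt$mn_parent
    labels <- c(labels, has)
  }
  n <- length(labels)
  expect_gte(n, 60)
  expect_lt(abs(mean(labels) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("sorted-population model has the closed-form limits", {
  perfect <- sorted_population_model(0.078, 1, 1, sort_accuracy = 1)
  expect_equal(perfect$purity_pos, 1.0)
  expect_equal(perfect$enrichment, 1 / 0.078)
  for (s in c(0.5, 0.8, 0.95)) {
    unif <- sorted_population_model(0.078, 0.5, 0.5, s)
    expect_equal(unif$purity_pos, 0.078)
    expect_equal(unif$enrichment, 1.0)
  }
  expect_true(is.na(sorted_population_model(0, 1, 1, 1)$enrichment))
})

test_that("sorted-population model agrees with Monte-Carlo simulation", {
  p <- sorted_population_model(0.078, 0.83, 0.82, 0.95)
  set.seed(123)
  n <- 4e5
  is_pos <- runif(n) < 0.078
  labeled_pos <- ifelse(is_pos, runif(n) < 0.83, runif(n) < (1 - 0.82))
  in_pos_bin <- ifelse(labeled_pos, runif(n) < 0.95, runif(n) < 0.05)
  sim_purity <- mean(is_pos[in_pos_bin])
  expect_equal(p$purity_pos, sim_purity, tolerance = 0.02)
  expect_equal(p$enrichment, sim_purity / 0.078, tolerance = 0.02)
  # purity is monotone non-decreasing in each argument over a parameter grid
  pur <- function(rp, rn, s) sorted_population_model(0.1, rp, rn, s)$purity_pos
  levels <- c(0.6, 0.8, 0.95)
  for (a in levels) {
    for (b in levels) {
      expect_true(all(diff(vapply(levels, function(x) pur(x, a, b), numeric(1))) >= 0))
      expect_true(all(diff(vapply(levels, function(x) pur(a, x, b), numeric(1))) >= 0))
      expect_true(all(diff(vapply(levels, function(x) pur(a, b, x), numeric(1))) >= 0))
    }
  }
})

test_that("drift adjustment is multiplicative, monotone and bounded", {
  expect_equal(adjust_ppv_for_drift(0.85, 0), 0.85)
  expect_equal(adjust_ppv_for_drift(1, 0.1), 0.9)
  expect_equal(adjust_ppv_for_drift(0.706, 0.123), 0.706 * (1 - 0.123))
  d <- seq(0, 1, by = 0.1)
  v <- vapply(d, function(x) adjust_ppv_for_drift(0.706, x), numeric(1))
  expect_true(all(diff(v) < 0))
  expect_true(all(v >= 0 & v <= 0.706))
})
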