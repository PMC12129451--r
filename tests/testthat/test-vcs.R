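test_that("builtin nucleus segmenter handles blank, clean and touching cases", {
  cfg <- mn_config()
  expect_length(mask_labels(segment_nuclei_builtin(matrix(0, 64, 64), cfg)), 0L)
  f <- generate_field(synth_config(seed = 2))
  nm <- segment_nuclei_builtin(get_channel(f$image, "chromatin"), cfg)
  true_ids <- mask_labels(f$gt$nucleus_mask)
  expect_equal(length(mask_labels(nm)), length(true_ids))
  for (id in true_ids) {
    ov <- table(nm[f$gt$nucleus_mask == id]); ov <- ov[names(ov) != "0"]
    expect_gt(length(ov), 0)
    pid <- as.integer(names(which.max(ov)))
    inter <- sum(nm == pid & f$gt$nucleus_mask == id)
    uni <- sum(nm == pid | f$gt$nucleus_mask == id)
    expect_gte(inter / uni, 0.9)
  }
  # two touching ellipses are split by the distance-transform watershed
  chrom <- matrix(0, 80, 80)
  chrom <- draw_disc(chrom, 40, 28, 12, 1)
  chrom <- draw_disc(chrom, 40, 50, 12, 1)
  chrom <- chrom * 0.8 + 0.02
  split <- segment_nuclei_builtin(chrom, cfg)
  expect_equal(length(mask_labels(split)), 2L)
})

test_that("crop classification maps oracle MN back within a 1 px tolerance", {
  cfg <- mn_config()
  # constructed field: the MN lies fully inside the nucleus-centered window,
  # so the enlarge/shrink round trip must reproduce it within 1 px dilation
  nuc <- draw_disc(matrix(0L, 120, 120), 60, 60, 11, 1L)
  mn <- draw_disc(matrix(0L, 120, 120), 60, 78, 3, 1L)
  gt <- make_gt(nuc, mn, c(1L))
  pred <- classify_field_vcs(matrix(0.02, 120, 120), nuc,
                             oracle_vcs_model(gt), cfg) > 0
  truth <- mn > 0
  expect_true(all(which(pred) %in% which(mnseg:::.touches(truth))))
  expect_true(all(which(truth) %in% which(mnseg:::.touches(pred))))
  # on generated fields most MN pixels are recovered (MN can protrude from
  # the fixed-size window when far from its nucleus)
  f <- generate_field(synth_config(seed = 4, mn_frequency = 1))
  mn_pred <- classify_field_vcs(f$image, f$gt$nucleus_mask,
                                oracle_vcs_model(f$gt), cfg)
  tr <- f$gt$mn_mask > 0
  covered <- tr & mnseg:::.touches(mn_pred > 0)
  expect_gte(sum(covered) / sum(tr), 0.65)
  # no nuclei means no MN, regardless of the model
  none <- classify_field_vcs(f$image, matrix(0L, 256, 256),
                             oracle_vcs_model(f$gt), cfg)
  expect_length(mask_labels(none), 0L)
})

test_that("an MN seen from two adjacent crops stays a single component", {
  cfg <- mn_config()
  chrom <- matrix(0.02, 120, 120)
  nuc <- matrix(0L, 120, 120)
  nuc <- draw_disc(nuc, 50, 40, 10, 1L)
  nuc <- draw_disc(nuc, 50, 70, 10, 2L)
  mn <- draw_disc(matrix(0L, 120, 120), 50, 55, 3, 1L)  # between both nuclei
  gt <- make_gt(nuc, mn, c(1L))
  pred <- classify_field_vcs(chrom, nuc, oracle_vcs_model(gt), cfg)
  expect_length(mask_labels(pred), 1L)
})

test_that("assignment respects the 40 px discard rule at both sides of the boundary", {
  cfg <- mn_config()
  mk <- function(gap) {
    nuc <- matrix(0L, 160, 160); nuc[70:90, 30:50] <- 1L
    mn <- matrix(0L, 160, 160); mn[79:81, 50 + gap + 0:2] <- 1L
    list(nuc = nuc, mn = mn)
  }
  a39 <- mk(39); r39 <- assign_mn(a39$mn, a39$nuc, cfg)
  expect_false(r39$discarded)
  expect_equal(r39$nucleus_id, 1L)
  expect_equal(r39$distance, 39)
  a41 <- mk(41); r41 <- assign_mn(a41$mn, a41$nuc, cfg)
  expect_true(r41$discarded)
  expect_equal(r41$reason, "too_far")
  a40 <- mk(40); expect_false(assign_mn(a40$mn, a40$nuc, cfg)$discarded)
  # MN entirely inside a nucleus is discarded
  inside <- matrix(0L, 160, 160); inside[75:77, 35:37] <- 1L
  ri <- assign_mn(inside, a39$nuc, cfg)
  expect_true(ri$discarded)
  expect_equal(ri$reason, "within_nucleus")
})

test_that("assignments equal the brute-force all-pairs minimum distance", {
  cfg <- mn_config()
  set.seed(61)
  for (rep in 1:5) {
    n <- 64
    nuc <- random_blob_mask(n, 3, rmin = 4, rmax = 6)
    mn <- matrix(0L, n, n)
    for (k in 1:3) {
      mn <- draw_disc(mn, runif(1, 5, n - 5), runif(1, 5, n - 5), 2, k)
    }
    mn[nuc > 0] <- 0L
    res <- assign_mn(mn, nuc, cfg)
    for (i in seq_len(nrow(res))) {
      id <- res$mn_id[i]
      if (sum(mn == id) == 0) next
      ds <- vapply(mask_labels(nuc), function(nid) {
        bf_min_distance(mn, id, nuc, nid)
      }, numeric(1))
      if (all(nuc[mn == id] > 0)) {
        expect_true(res$discarded[i])
      } else if (min(ds) > cfg$mn_discard_radius) {
        expect_true(res$discarded[i])
      } else {
        expect_equal(res$distance[i], min(ds))
        expect_equal(res$nucleus_id[i],
                     mask_labels(nuc)[which.min(ds)])
      }
    }
  }
})

test_that("rupture calls sit strictly below the 0.16 boundary and scale-invariantly", {
  cfg <- mn_config()
  nuc <- matrix(0L, 40, 40); nuc[5:15, 5:15] <- 1L
  mn <- matrix(0L, 40, 40); mn[25:27, 25:27] <- 1L
  mk_rep <- function(ratio) {
    rep_ch <- matrix(0, 40, 40)
    rep_ch[nuc == 1L] <- 1
    rep_ch[mn == 1L] <- ratio
    rep_ch
  }
  expect_equal(classify_rupture(1L, 1L, mk_rep(0.159), mn, nuc, cfg), "ruptured")
  expect_equal(classify_rupture(1L, 1L, mk_rep(0.160), mn, nuc, cfg), "intact")
  # multiplying the reporter channel by a positive constant changes nothing
  for (k in c(0.2, 7)) {
    expect_equal(classify_rupture(1L, 1L, mk_rep(0.159) * k, mn, nuc, cfg),
                 "ruptured")
  }
  expect_error(classify_rupture(1L, 1L, mk_rep(0) * 0, mn, nuc, cfg), "zero")
})

test_that("nucleus labels follow the MN+/rupture+ rules", {
  asg <- data.frame(mn_id = c(1L, 2L, 3L),
                    nucleus_id = c(2L, 3L, 3L),
                    ruptured = c(FALSE, FALSE, TRUE))
  lab <- label_nuclei(1:3, asg)
  expect_equal(lab$mn_status, c("MN-", "MN+", "MN+"))
  expect_equal(lab$rupture_status, c(NA, "rupture-", "rupture+"))
  # two intact MN: MN+, rupture-
  asg2 <- data.frame(mn_id = 1:2, nucleus_id = c(1L, 1L),
                     ruptured = c(FALSE, FALSE))
  expect_equal(label_nuclei(1L, asg2)$rupture_status, "rupture-")
})

test_that("threshold fitting matches an exhaustive sweep and separable data", {
  fit <- fit_rupture_threshold(c(0.05, 0.10, 0.5, 0.9),
                               c(TRUE, TRUE, FALSE, FALSE))
  expect_gt(fit$threshold, 0.10)
  expect_lt(fit$threshold, 0.5)
  expect_equal(fit$accuracy, 1.0)
  set.seed(17)
  ratios <- runif(60)
  labels <- runif(60) < 0.5
  fit2 <- fit_rupture_threshold(ratios, labels)
  u <- sort(unique(ratios))
  cand <- (u[-1] + u[-length(u)]) / 2
  accs <- vapply(cand, function(t_) mean((ratios < t_) == labels), numeric(1))
  expect_equal(fit2$accuracy, max(accs))
  expect_equal(fit2$threshold, cand[which(accs == max(accs))[1]])
  expect_error(fit_rupture_threshold(c(0.1, 0.2), c(TRUE, TRUE)), "both")
})

test_that("the full rapid pipeline reproduces ground-truth labels with oracles", {
  f <- generate_field(synth_config(seed = 10, mn_frequency = 0.8))
  res <- vcs_classify_field(f$image, oracle_vcs_model(f$gt),
                            nucleus_mask = f$gt$nucleus_mask)
  truth_labels <- label_nuclei(
    mask_labels(f$gt$nucleus_mask),
    data.frame(mn_id = as.integer(names(f$gt$mn_parent)),
               nucleus_id = unname(f$gt$mn_parent),
               ruptured = unname(f$gt$mn_ruptured)))
  m <- nucleus_classification_metrics(res$labels, truth_labels)
  expect_equal(m$`MN+`$recall, 1.0)
  expect_equal(m$`MN+`$ppv, 1.0)
  expect_equal(m$`rupture+`$recall, 1.0)
  expect_equal(m$`rupture+`$ppv, 1.0)
  # binary targeting masks are exclusive and binary
  masks <- class_masks(res, by = "mn")
  expect_true(all(masks$`MN+` %in% c(TRUE, FALSE)))
  expect_equal(sum(masks$`MN+` & masks$`MN-`), 0L)
})
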