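# Object-level evaluation (single-pixel-overlap detection rule, per-object
# mIoU, nucleus classification metrics, MN frequency) and the closed-form
# sorted-population purity / enrichment models.

#' Match predicted and ground-truth objects by pixel overlap
#'
#' A single pixel of overlap suffices: a ground-truth object counts as
#' recalled iff at least one predicted object overlaps it, and a predicted
#' object counts as a true positive iff it overlaps at least one ground-truth
#' object. Many-to-one matches are allowed on both sides.
#'
#' @param pred,gt Instance label matrices of equal dimension.
#' @return List with `tp`, `fp`, `fn` counts, `recall`, `ppv`, and `pairs`
#'   (data.frame `gt_id` / `pred_id` of every overlapping pair).
#' @export
match_objects <- function(pred, gt) {
  stopifnot(identical(dim(pred), dim(gt)))
  both <- pred > 0 & gt > 0
  pairs <- if (any(both)) {
    unique(data.frame(gt_id = gt[both], pred_id = pred[both]))
  } else {
    data.frame(gt_id = integer(0), pred_id = integer(0))
  }
  gt_ids <- mask_labels(gt)
  pred_ids <- mask_labels(pred)
  recalled <- gt_ids %in% pairs$gt_id
  tp_pred <- pred_ids %in% pairs$pred_id
  tp <- sum(tp_pred)
  fp <- sum(!tp_pred)
  fn <- sum(!recalled)
  list(tp = tp, fp = fp, fn = fn,
       recall = if (length(gt_ids) > 0) mean(recalled) else NA_real_,
       ppv = if (length(pred_ids) > 0) mean(tp_pred) else NA_real_,
       pairs = pairs)
}

#' Per-object mean intersection-over-union
#'
#' For every matched ground-truth object, the IoU between its pixel set and
#' the union of all predicted objects matched to it; the mean is taken over
#' matched ground-truth objects only (unmatched objects affect recall, not
#' mIoU).
#'
#' @param pred,gt Instance label matrices.
#' @param matches Optional precomputed [match_objects()] result.
#' @return Mean IoU fraction, or `NA` if there are no matches.
#' @export
per_object_miou <- function(pred, gt, matches = NULL) {
  if (is.null(matches)) matches <- match_objects(pred, gt)
  pairs <- matches$pairs
  if (nrow(pairs) == 0) return(NA_real_)
  ious <- vapply(unique(pairs$gt_id), function(g) {
    gt_px <- which(gt == g)
    preds <- pairs$pred_id[pairs$gt_id == g]
    pred_px <- which(pred %in% preds)
    length(intersect(gt_px, pred_px)) / length(union(gt_px, pred_px))
  }, numeric(1))
  mean(ious)
}

#' Per-class recall and PPV for nucleus-level labels
#'
#' Compares predicted and true MN+/MN- labels over the same nuclei, and
#' (among true-and-predicted MN+ nuclei with rupture information) the
#' rupture+/rupture- labels.
#'
#' @param pred,truth [nucleus_labels()] data.frames over the same nucleus ids.
#' @return Nested list: for each class (`MN+`, `MN-`, and when available
#'   `rupture+`, `rupture-`) the `recall` and `ppv`.
#' @export
nucleus_classification_metrics <- function(pred, truth) {
  if (!setequal(pred$nucleus_id, truth$nucleus_id)) {
    stop("prediction and truth must cover the same nucleus ids", call. = FALSE)
  }
  m <- match(truth$nucleus_id, pred$nucleus_id)
  p_mn <- pred$mn_status[m]
  t_mn <- truth$mn_status
  one_class <- function(p, t, cls) {
    tp <- sum(p == cls & t == cls, na.rm = TRUE)
    fn <- sum(p != cls & t == cls, na.rm = TRUE)
    fp <- sum(p == cls & t != cls, na.rm = TRUE)
    list(recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  }
  out <- list(`MN+` = one_class(p_mn, t_mn, "MN+"),
              `MN-` = one_class(p_mn, t_mn, "MN-"))
  p_r <- pred$rupture_status[m]
  t_r <- truth$rupture_status
  sel <- !is.na(p_r) & !is.na(t_r)
  if (any(sel)) {
    out$`rupture+` <- one_class(p_r[sel], t_r[sel], "rupture+")
    out$`rupture-` <- one_class(p_r[sel], t_r[sel], "rupture-")
  }
  out
}

#' Micronucleation frequency
#'
#' Proportion of nuclei with at least one associated MN.
#'
#' @param labels A [nucleus_labels()] data.frame.
#' @return Fraction in `[0, 1]`, or `NA` for zero nuclei.
#' @export
mn_frequency <- function(labels) {
  if (nrow(labels) == 0) return(NA_real_)
  mean(labels$mn_status == "MN+")
}

#' Closed-form sorted-population purity and enrichment model
#'
#' Decomposes a population with MN+ frequency `f` by classifier performance
#' (per-class recall) into true/false positives and negatives, then mixes the
#' labeled-positive and labeled-negative pools through an imperfect sorter:
#' the MN+ bin receives a fraction `sort_accuracy` of the labeled-positive
#' pool and `1 - sort_accuracy` of the labeled-negative pool (and conversely
#' for the MN- bin). Purity is the fraction of truly MN+ (resp. MN-) cells in
#' each bin; enrichment is MN+ purity over the starting frequency. Classifier
#' and sorter errors are treated as independent.
#'
#' @param f MN+ frequency of the starting population.
#' @param recall_pos,recall_neg Classifier recall for the MN+ and MN- classes.
#' @param sort_accuracy Probability that a labeled cell lands in its intended
#'   bin. Default 0.95.
#' @return List with `purity_pos`, `purity_neg`, `enrichment`.
#' @export
sorted_population_model <- function(f, recall_pos, recall_neg,
                                    sort_accuracy = 0.95) {
  stopifnot(f >= 0, f <= 1, recall_pos >= 0, recall_pos <= 1,
            recall_neg >= 0, recall_neg <= 1,
            sort_accuracy >= 0, sort_accuracy <= 1)
  tp <- f * recall_pos
  fn <- f * (1 - recall_pos)
  tn <- (1 - f) * recall_neg
  fp <- (1 - f) * (1 - recall_neg)
  s <- sort_accuracy
  pos_bin_pos <- s * tp + (1 - s) * fn       # truly MN+ cells in the MN+ bin
  pos_bin_tot <- s * (tp + fp) + (1 - s) * (fn + tn)
  neg_bin_neg <- s * tn + (1 - s) * fp
  neg_bin_tot <- s * (fn + tn) + (1 - s) * (tp + fp)
  purity_pos <- if (pos_bin_tot > 0) pos_bin_pos / pos_bin_tot else NA_real_
  purity_neg <- if (neg_bin_tot > 0) neg_bin_neg / neg_bin_tot else NA_real_
  list(purity_pos = purity_pos, purity_neg = purity_neg,
       enrichment = if (f > 0) purity_pos / f else NA_real_)
}

#' Adjust a rupture-class PPV for rupture drift during an experiment
#'
#' Intact MN that rupture between labeling and sorting convert true positives
#' of the rupture- pool into false positives: with drift fraction `d`, the
#' adjusted PPV is `ppv * (1 - d)`.
#'
#' @param ppv Positive predictive value in `[0, 1]`.
#' @param d Drift fraction in `[0, 1]` (increase in mean rupture frequency
#'   over the experiment).
#' @return Adjusted PPV.
#' @export
adjust_ppv_for_drift <- function(ppv, d) {
  stopifnot(ppv >= 0, ppv <= 1, d >= 0, d <= 1)
  ppv * (1 - d)
}

#' Evaluate a segmentation against ground truth
#'
#' Convenience wrapper computing MN detection recall/PPV, per-object mIoU and
#' counts for one field.
#'
#' @param pred_mn Predicted MN label matrix.
#' @param gt A [ground_truth()] or an MN label matrix.
#' @return List of metrics (see [match_objects()], [per_object_miou()]).
#' @export
evaluate_mn_segmentation <- function(pred_mn, gt) {
  gt_mask <- if (inherits(gt, "ground_truth")) gt$mn_mask else gt
  m <- match_objects(pred_mn, gt_mask)
  list(tp = m$tp, fp = m$fp, fn = m$fn, recall = m$recall, ppv = m$ppv,
       miou = per_object_miou(pred_mn, gt_mask, m))
}
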