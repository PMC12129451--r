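# Brute-force reference implementations used across the suite. These are
# deliberately naive O(N^2) (or worse) computations, independent of the
# package's algorithms, against which the fast paths are checked.

# exhaustive per-pixel distance to the nearest TRUE target pixel
bf_edt <- function(target) {
  n <- nrow(target); m <- ncol(target)
  idx <- which(target)
  out <- matrix(Inf, n, m)
  if (length(idx) == 0) return(out)
  rr <- ((idx - 1) %% n) + 1
  cc <- ((idx - 1) %/% n) + 1
  for (r in seq_len(n)) {
    dr2 <- (r - rr)^2
    for (c2 in seq_len(m)) {
      out[r, c2] <- sqrt(min(dr2 + (c2 - cc)^2))
    }
  }
  out
}

# brute-force filled convex hull: a pixel center is inside iff adding it to
# the point set leaves the hull area unchanged
bf_hull_mask <- function(mask) {
  n <- nrow(mask)
  idx <- which(mask > 0)
  rr <- ((idx - 1) %% n) + 1
  cc <- ((idx - 1) %/% n) + 1
  shoelace <- function(r, c2) {
    h <- grDevices::chull(r, c2)
    vr <- r[h]; vc <- c2[h]
    k <- length(vr)
    abs(sum(vr * vc[c(2:k, 1)] - vr[c(2:k, 1)] * vc)) / 2
  }
  base_area <- shoelace(rr, cc)
  out <- matrix(FALSE, n, ncol(mask))
  for (r in min(rr):max(rr)) {
    for (c2 in min(cc):max(cc)) {
      out[r, c2] <- shoelace(c(rr, r), c(cc, c2)) <= base_area + 1e-9
    }
  }
  out
}

# exhaustive object matching under the single-pixel-overlap rule
bf_match <- function(pred, gt) {
  gt_ids <- sort(unique(gt[gt > 0]))
  pred_ids <- sort(unique(pred[pred > 0]))
  overlaps <- function(a_mask, b_mask) any(a_mask & b_mask)
  recalled <- vapply(gt_ids, function(g) {
    any(vapply(pred_ids, function(p) overlaps(gt == g, pred == p), logical(1)))
  }, logical(1))
  tp_pred <- vapply(pred_ids, function(p) {
    any(vapply(gt_ids, function(g) overlaps(gt == g, pred == p), logical(1)))
  }, logical(1))
  list(tp = sum(tp_pred), fp = sum(!tp_pred), fn = sum(!recalled),
       recall = if (length(gt_ids)) mean(recalled) else NA_real_,
       ppv = if (length(pred_ids)) mean(tp_pred) else NA_real_)
}

# exhaustive minimum pixel-pair distance between two labeled objects
bf_min_distance <- function(mask_a, id_a, mask_b, id_b) {
  n <- nrow(mask_a)
  ia <- which(mask_a == id_a); ib <- which(mask_b == id_b)
  ra <- ((ia - 1) %% n) + 1; ca <- ((ia - 1) %/% n) + 1
  rb <- ((ib - 1) %% n) + 1; cb <- ((ib - 1) %/% n) + 1
  sqrt(min(outer(ra, rb, "-")^2 + outer(ca, cb, "-")^2))
}

# random instance mask of a few disc-shaped blobs (labels 1..k)
random_blob_mask <- function(n, k, rmin = 2, rmax = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(0L, n, n)
  for (i in seq_len(k)) {
    r0 <- runif(1, rmax + 1, n - rmax)
    c0 <- runif(1, rmax + 1, n - rmax)
    rad <- runif(1, rmin, rmax)
    for (r in max(1, floor(r0 - rad)):min(n, ceiling(r0 + rad))) {
      for (c2 in max(1, floor(c0 - rad)):min(n, ceiling(c0 + rad))) {
        if ((r - r0)^2 + (c2 - c0)^2 <= rad^2) mask[r, c2] <- i
      }
    }
  }
  mask
}

# small ground truth built from explicit masks (for constructed fixtures)
make_gt <- function(nuc, mn, parent, ruptured = NULL) {
  mn_ids <- sort(unique(mn[mn > 0]))
  if (is.null(ruptured)) ruptured <- rep(FALSE, length(mn_ids))
  names(parent) <- mn_ids
  names(ruptured) <- mn_ids
  ground_truth(nuc, mn, parent, ruptured)
}

# draw a filled disc into an integer mask
draw_disc <- function(mask, r0, c0, rad, label) {
  for (r in max(1, floor(r0 - rad)):min(nrow(mask), ceiling(r0 + rad))) {
    for (c2 in max(1, floor(c0 - rad)):min(ncol(mask), ceiling(c0 + rad))) {
      if ((r - r0)^2 + (c2 - c0)^2 <= rad^2) mask[r, c2] <- label
    }
  }
  mask
}
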