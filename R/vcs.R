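# The rapid nucleus-crop pipeline: pluggable nucleus segmentation, per-crop
# MN prediction mapped back to the field, proximity-based MN assignment with
# discard rules, reporter-ratio rupture classification, and nucleus-level
# MN+/MN- and rupture+/rupture- labels.

#' Built-in nucleus segmenter
#'
#' Otsu threshold on the chromatin channel, hole filling, removal of objects
#' below the nucleus area threshold, and a distance-transform watershed split
#' of touching nuclei. Any external segmenter returning an instance mask can
#' be used in its place throughout the pipeline.
#'
#' @param chrom Chromatin channel matrix.
#' @param config An [mn_config()].
#' @param watershed_tolerance Minimum height of an object's distance-map
#'   maximum for it to stay a separate nucleus. Default 1.
#' @return Integer nucleus label matrix.
#' @export
segment_nuclei_builtin <- function(chrom, config = mn_config(),
                                   watershed_tolerance = 1) {
  rng <- range(chrom)
  if (rng[2] <= rng[1]) return(matrix(0L, nrow(chrom), ncol(chrom)))
  xn <- (chrom - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  bin <- xn > th
  bin <- as.matrix(EBImage::fillHull(EBImage::Image(bin * 1))) > 0
  lab <- label_components(bin)
  areas <- mask_areas(lab)
  drop <- as.integer(names(areas)[areas < config$nucleus_min_area])
  if (length(drop) > 0) lab[lab %in% drop] <- 0L
  if (!any(lab > 0)) return(matrix(0L, nrow(chrom), ncol(chrom)))
  dm <- edt_exact(lab == 0L)
  dm[is.infinite(dm)] <- max(dim(chrom))
  wat <- EBImage::watershed(EBImage::Image(dm * (lab > 0)),
                            tolerance = watershed_tolerance)
  out <- matrix(as.integer(wat), nrow(chrom))
  # watershed may resurrect sub-threshold fragments; re-apply the area floor
  areas <- mask_areas(out)
  drop <- as.integer(names(areas)[areas < config$nucleus_min_area])
  if (length(drop) > 0) out[out %in% drop] <- 0L
  labs <- mask_labels(out)
  dense <- match(out, c(0L, labs)) - 1L
  matrix(as.integer(dense), nrow(chrom))
}

#' Oracle crop-classifier backend
#'
#' Test double for the crop classifier: given the ground truth it returns, for
#' any crop window, the true MN mask enlarged to the net input size.
#'
#' @param gt A [ground_truth()].
#' @return An object of class `mn_oracle_vcs`.
#' @export
oracle_vcs_model <- function(gt) {
  structure(list(mn = (gt$mn_mask > 0) * 1), class = "mn_oracle_vcs")
}

# MN probability map (net-input scale) for one crop
.vcs_crop_probs <- function(model, crop, window, config) {
  ns <- config$vcs_net_input_size
  if (inherits(model, "mn_oracle_vcs")) {
    s <- window["size"]
    h <- nrow(model$mn); w <- ncol(model$mn)
    sub <- matrix(0, s, s)
    rows <- window["row0"]:min(window["row0"] + s - 1, h)
    cols <- window["col0"]:min(window["col0"] + s - 1, w)
    sub[seq_along(rows), seq_along(cols)] <- model$mn[rows, cols]
    .resize_nearest(sub, ns)
  } else {
    pr <- predict_tile_probs(model, crop)
    pr[, , 3]
  }
}

#' Classify a field with the nucleus-crop pipeline
#'
#' For every nucleus, builds the three-channel crop ([make_vcs_crop()]), runs
#' the crop model, maps predicted MN pixels back to field coordinates
#' (inverting the crop enlargement), merges overlapping crop predictions by
#' union, and labels connected MN components.
#'
#' @param image [field_image()] or chromatin matrix.
#' @param nucleus_mask Instance nucleus mask.
#' @param model Crop model (`mn_pixel_model` with 3-channel input, or
#'   [oracle_vcs_model()]).
#' @param config An [mn_config()].
#' @param threshold MN-probability binarization threshold. Default 0.5.
#' @return Integer MN label matrix.
#' @export
classify_field_vcs <- function(image, nucleus_mask, model,
                               config = mn_config(), threshold = 0.5) {
  chrom <- if (inherits(image, "field_image")) get_channel(image, "chromatin") else image
  mn_bin <- matrix(FALSE, nrow(chrom), ncol(chrom))
  for (id in mask_labels(nucleus_mask)) {
    crop <- make_vcs_crop(chrom, nucleus_mask, id, config)
    probs <- .vcs_crop_probs(model, crop$data, crop$window, config)
    small <- .resize_nearest(probs, config$vcs_crop_size) > threshold
    w <- crop$window
    rows <- w["row0"]:min(w["row0"] + w["size"] - 1, nrow(chrom))
    cols <- w["col0"]:min(w["col0"] + w["size"] - 1, ncol(chrom))
    mn_bin[rows, cols] <- mn_bin[rows, cols] |
      small[seq_along(rows), seq_along(cols)]
  }
  mn_bin[nucleus_mask > 0] <- FALSE   # MN pixels inside nuclei are not MN
  label_components(mn_bin)
}

#' Assign micronuclei to their nearest nucleus
#'
#' Distance is the minimum Euclidean distance between mask pixels (boundary to
#' boundary). An MN is assigned to the nearest nucleus if that distance is at
#' most `config$mn_discard_radius` and discarded otherwise (strictly farther
#' than the radius); MN lying entirely within a nucleus mask are discarded as
#' well. Ties go to the lower nucleus label.
#'
#' @param mn_mask,nucleus_mask Label matrices of equal dimension.
#' @param config An [mn_config()].
#' @return data.frame with one row per MN: `mn_id`, `nucleus_id` (NA if
#'   discarded), `distance`, `discarded`, `reason`.
#' @export
assign_mn <- function(mn_mask, nucleus_mask, config = mn_config()) {
  stopifnot(identical(dim(mn_mask), dim(nucleus_mask)))
  mn_ids <- mask_labels(mn_mask)
  out <- data.frame(mn_id = mn_ids, nucleus_id = NA_integer_,
                    distance = NA_real_, discarded = FALSE,
                    reason = NA_character_)
  if (length(mn_ids) == 0) return(out)
  inside <- vapply(mn_ids, function(id) all(nucleus_mask[mn_mask == id] > 0),
                   logical(1))
  D <- .mn_nucleus_distances(mn_mask, nucleus_mask)
  for (i in seq_along(mn_ids)) {
    if (inside[i]) {
      out$discarded[i] <- TRUE
      out$reason[i] <- "within_nucleus"
      next
    }
    if (ncol(D) == 0) {
      out$discarded[i] <- TRUE
      out$reason[i] <- "no_nucleus"
      next
    }
    j <- which.min(D[i, ])  # which.min takes the first (lowest label) on ties
    out$distance[i] <- D[i, j]
    if (D[i, j] > config$mn_discard_radius) {
      out$discarded[i] <- TRUE
      out$reason[i] <- "too_far"
    } else {
      out$nucleus_id[i] <- as.integer(colnames(D)[j])
    }
  }
  out
}

#' Classify a micronucleus as intact or ruptured
#'
#' Computes the ratio of the maximum reporter intensity over the MN pixels to
#' the maximum over its nucleus' pixels; the MN is ruptured iff the ratio is
#' strictly below `config$rupture_ratio_threshold` (0.16 by default). The call
#' is invariant to any positive rescaling of the reporter channel.
#'
#' @param mn_id,nucleus_id Labels of the MN and its assigned nucleus.
#' @param reporter Reporter channel matrix.
#' @param mn_mask,nucleus_mask Label matrices.
#' @param config An [mn_config()].
#' @return `"intact"` or `"ruptured"`.
#' @export
classify_rupture <- function(mn_id, nucleus_id, reporter, mn_mask,
                             nucleus_mask, config = mn_config()) {
  mn_px <- reporter[mn_mask == mn_id]
  nuc_px <- reporter[nucleus_mask == nucleus_id]
  if (length(mn_px) == 0 || length(nuc_px) == 0) {
    stop("empty mask for MN ", mn_id, " or nucleus ", nucleus_id, call. = FALSE)
  }
  nuc_max <- max(nuc_px)
  if (nuc_max <= 0) {
    stop("nucleus ", nucleus_id, " has zero reporter intensity; ratio undefined",
         call. = FALSE)
  }
  ratio <- max(mn_px) / nuc_max
  if (ratio < config$rupture_ratio_threshold) "ruptured" else "intact"
}

#' Nucleus-level labels from assignments and rupture calls
#'
#' A nucleus is MN+ iff at least one MN is assigned to it; an MN+ nucleus is
#' rupture+ iff at least one of its MN is ruptured, rupture- if all are
#' intact, and has rupture status NA when rupture was not evaluated.
#'
#' @param nucleus_ids Integer labels of all nuclei.
#' @param assignments data.frame with `mn_id`, `nucleus_id` and optionally
#'   `ruptured` (logical).
#' @return A [nucleus_labels()] data.frame.
#' @export
label_nuclei <- function(nucleus_ids, assignments) {
  mn_ids <- lapply(nucleus_ids, function(id) {
    as.integer(assignments$mn_id[!is.na(assignments$nucleus_id) &
                                   assignments$nucleus_id == id])
  })
  mn_status <- ifelse(vapply(mn_ids, length, integer(1)) >= 1, "MN+", "MN-")
  has_rupture_info <- "ruptured" %in% names(assignments) &&
    !all(is.na(assignments$ruptured))
  rupture_status <- vapply(seq_along(nucleus_ids), function(i) {
    if (mn_status[i] == "MN-") return(NA_character_)
    if (!has_rupture_info) return("rupture-")
    r <- assignments$ruptured[match(mn_ids[[i]], assignments$mn_id)]
    if (any(r %in% TRUE)) "rupture+" else "rupture-"
  }, character(1))
  nucleus_labels(nucleus_ids, mn_status, rupture_status, mn_ids)
}

#' Fit the rupture-ratio decision threshold from labeled data
#'
#' One-dimensional decision stump: sweeps the midpoints of adjacent sorted
#' ratio values and returns the threshold (rupture iff ratio < threshold)
#' that maximizes classification accuracy; ties resolve to the lowest
#' threshold.
#'
#' @param ratios Numeric MN/nucleus reporter intensity ratios.
#' @param ruptured Logical labels (TRUE = ruptured).
#' @return List with `threshold` and `accuracy`.
#' @export
fit_rupture_threshold <- function(ratios, ruptured) {
  stopifnot(length(ratios) == length(ruptured))
  if (length(unique(ruptured)) < 2) {
    stop("both intact and ruptured examples are required", call. = FALSE)
  }
  u <- sort(unique(ratios))
  cand <- (u[-1] + u[-length(u)]) / 2
  acc <- vapply(cand, function(t_) mean((ratios < t_) == ruptured), numeric(1))
  best <- which(acc == max(acc))[1]
  list(threshold = cand[best], accuracy = acc[best])
}

#' Run the rapid crop-classifier pipeline on a field
#'
#' Segments nuclei (built-in segmenter unless one is injected), predicts MN
#' around each nucleus, assigns MN by proximity with the discard rules,
#' optionally classifies rupture from the reporter channel, and labels nuclei.
#'
#' @param image A [field_image()].
#' @param model Crop model or [oracle_vcs_model()].
#' @param config An [mn_config()].
#' @param nucleus_mask Optional precomputed nucleus mask (pluggable external
#'   segmenter).
#' @param classify_rupture_calls Classify rupture if a reporter channel is
#'   present. Default `TRUE`.
#' @return List of class `vcs_result`: `nucleus_mask`, `mn_mask`,
#'   `assignments`, `labels`.
#' @export
vcs_classify_field <- function(image, model, config = mn_config(),
                               nucleus_mask = NULL,
                               classify_rupture_calls = TRUE) {
  chrom <- get_channel(image, "chromatin")
  if (is.null(nucleus_mask)) {
    nucleus_mask <- segment_nuclei_builtin(chrom, config)
  }
  mn_mask <- classify_field_vcs(image, nucleus_mask, model, config)
  assign <- assign_mn(mn_mask, nucleus_mask, config)
  has_reporter <- "reporter" %in% names(image$channels)
  assign$ruptured <- NA
  if (classify_rupture_calls && has_reporter) {
    rep_ch <- get_channel(image, "reporter")
    keep <- !assign$discarded
    assign$ruptured[keep] <- vapply(which(keep), function(i) {
      classify_rupture(assign$mn_id[i], assign$nucleus_id[i], rep_ch,
                       mn_mask, nucleus_mask, config) == "ruptured"
    }, logical(1))
  }
  labels <- label_nuclei(mask_labels(nucleus_mask),
                         assign[!assign$discarded, , drop = FALSE])
  structure(list(nucleus_mask = nucleus_mask, mn_mask = mn_mask,
                 assignments = assign, labels = labels),
            class = "vcs_result")
}

#' Binary per-class nucleus masks for photoconversion targeting
#'
#' One 1-bit mask per class: for `by = "mn"` the MN+ and MN- nucleus masks,
#' for `by = "rupture"` the rupture+ and rupture- masks (MN+ nuclei only).
#' Masks are mutually exclusive.
#'
#' @param result A `vcs_result`.
#' @param by `"mn"` or `"rupture"`.
#' @return Named list of logical matrices.
#' @export
class_masks <- function(result, by = c("mn", "rupture")) {
  by <- match.arg(by)
  lab <- result$labels
  nm <- result$nucleus_mask
  pick <- function(ids) {
    m <- matrix(FALSE, nrow(nm), ncol(nm))
    if (length(ids)) m[nm %in% ids] <- TRUE
    m
  }
  if (by == "mn") {
    list(`MN+` = pick(lab$nucleus_id[lab$mn_status == "MN+"]),
         `MN-` = pick(lab$nucleus_id[lab$mn_status == "MN-"]))
  } else {
    if (all(is.na(lab$rupture_status))) {
      stop("rupture classification was not performed (no reporter channel)",
           call. = FALSE)
    }
    list(`rupture+` = pick(lab$nucleus_id[lab$rupture_status %in% "rupture+"]),
         `rupture-` = pick(lab$nucleus_id[lab$rupture_status %in% "rupture-"]))
  }
}
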