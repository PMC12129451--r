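# Post-processing of the tiled segmenter's raw outputs: label filtering and
# morphology on the pixel-classifier maps, watershed cell segmentation from
# the distance/proximity maps, and integration into final nucleus / MN / cell
# labels with associations.

#' Reclassify small nucleus components as micronuclei
#'
#' Connected components of the nucleus mask with an area strictly below
#' `config$nucleus_min_area` (250 px by default) are moved to the MN mask
#' under fresh labels; larger components are untouched. Both masks are
#' returned relabeled by connected component.
#'
#' @param nucleus_mask,mn_mask Label (or binary) matrices; must be disjoint.
#' @param config An [mn_config()].
#' @return List with `nucleus_mask` and `mn_mask`.
#' @export
reclassify_small_nuclei <- function(nucleus_mask, mn_mask, config = mn_config()) {
  stopifnot(!any(nucleus_mask > 0 & mn_mask > 0))
  ncc <- label_components(nucleus_mask > 0)
  mcc <- label_components(mn_mask > 0)
  areas <- mask_areas(ncc)
  small <- as.integer(names(areas)[areas < config$nucleus_min_area])
  if (length(small) > 0) {
    base <- max(0L, mask_labels(mcc))
    base <- if (length(base) == 0) 0L else max(base)
    for (k in seq_along(small)) {
      idx <- ncc == small[k]
      mcc[idx] <- base + k
      ncc[idx] <- 0L
    }
    ncc <- label_components(ncc > 0)
  }
  list(nucleus_mask = ncc, mn_mask = mcc)
}

#' Expand micronucleus masks to their convex hulls
#'
#' Replaces every MN component by its filled convex hull to improve pixel
#' capture. Expansion never overwrites nucleus pixels or pixels of other MN;
#' pixels claimed by several expanding hulls go to the component with the
#' nearer original centroid (ties to the lower label).
#'
#' @param mn_mask Instance-labeled MN mask.
#' @param nucleus_mask Optional nucleus mask whose pixels are never claimed.
#' @return Expanded MN label matrix; a superset of the input labeling.
#' @export
expand_mn_to_hull <- function(mn_mask, nucleus_mask = NULL) {
  labs <- mask_labels(mn_mask)
  if (length(labs) == 0) return(mn_mask)
  h <- nrow(mn_mask)
  cents <- mask_centroids(mn_mask)
  out <- mn_mask
  claims <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    idx <- which(mn_mask == labs[i])
    rows <- ((idx - 1L) %% h) + 1L
    cols <- ((idx - 1L) %/% h) + 1L
    hull <- convex_hull_pixels(rows, cols, dim(mn_mask))
    new <- hull[mn_mask[hull] == 0]
    if (!is.null(nucleus_mask)) new <- new[nucleus_mask[new] == 0]
    claims[[i]] <- new
  }
  all_new <- unlist(claims)
  n_claims <- table(all_new)
  contested <- as.integer(names(n_claims)[n_claims > 1L])
  for (i in seq_along(labs)) {
    uncontested <- setdiff(claims[[i]], contested)
    out[uncontested] <- labs[i]
  }
  if (length(contested) > 0) {
    rr <- ((contested - 1L) %% h) + 1L
    cc <- ((contested - 1L) %/% h) + 1L
    best <- rep(0L, length(contested))
    bestd <- rep(Inf, length(contested))
    for (i in seq_along(labs)) {
      inclaim <- contested %in% claims[[i]]
      d <- (rr - cents[i, "row"])^2 + (cc - cents[i, "col"])^2
      take <- inclaim & (d < bestd)   # strict: ties stay with the lower label
      best[take] <- labs[i]
      bestd[take] <- d[take]
    }
    out[contested] <- best
  }
  out
}

#' Watershed cell segmentation from the map set
#'
#' Sums the distance and proximity maps, thresholds the sum for watershed
#' seeds, floods the inverted sum restricted to the foreground, and then
#' repairs oversegmentation: the boundary between two watershed objects is
#' kept only where it touches background or the skeleton of the low-proximity
#' interface band (foreground pixels with proximity below
#' `config$proximity_skeleton_threshold`); boundaries with no such support are
#' dissolved and the objects merged.
#'
#' @param maps An `mn_map_set` (see [make_map_set()] / [predict_map_set()]).
#' @param config An [mn_config()].
#' @return Integer cell label matrix (0 = background).
#' @export
segment_cells <- function(maps, config = mn_config()) {
  fg <- maps$foreground > 0.5
  s <- maps$distance + maps$proximity
  seeds <- s > config$cell_seed_threshold & fg
  if (!any(seeds)) return(matrix(0L, nrow(fg), ncol(fg)))
  seed_lab <- label_components(seeds)
  wat <- EBImage::propagate(EBImage::Image(1 - s / 2), seeds = seed_lab,
                            mask = fg)
  lab <- matrix(as.integer(wat), nrow(fg))

  # oversegmentation repair along unsupported boundaries
  band <- fg & (maps$proximity < config$proximity_skeleton_threshold)
  skel <- skeletonize(band)
  near_bg <- .touches(lab == 0L | !fg, edge = TRUE)
  near_skel <- skel | .touches(skel, edge = FALSE)

  pairs <- list()
  h <- nrow(lab); w <- ncol(lab)
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                 c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  bkey <- character(0)
  bsel <- integer(0)
  for (sh in shifts) {
    nb <- .shift_mat(lab, sh[1], sh[2], pad = 0L)
    sel <- which(lab > 0L & nb > 0L & lab != nb)
    if (length(sel) == 0) next
    a <- pmin(lab[sel], nb[sel])
    b <- pmax(lab[sel], nb[sel])
    bkey <- c(bkey, paste(a, b))
    bsel <- c(bsel, sel)
  }
  to_merge <- character(0)
  if (length(bsel) > 0) {
    # de-duplicate boundary pixels per pair, then require majority support:
    # a boundary survives only if at least half of its pixels sit on background
    # or on the interface skeleton; endpoint pixels alone cannot sustain a split
    dd <- !duplicated(paste(bkey, bsel))
    bkey <- bkey[dd]; bsel <- bsel[dd]
    ok <- near_bg[bsel] | near_skel[bsel]
    support <- tapply(ok, bkey, mean)
    to_merge <- names(support)[support < 0.5]
  }
  if (length(to_merge) > 0) {
    n_lab <- max(lab)
    parent <- seq_len(n_lab)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (k in to_merge) {
      ab <- as.integer(strsplit(k, " ")[[1]])
      ra <- find(ab[1]); rb <- find(ab[2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n_lab), find, integer(1))
    dense <- match(root, sort(unique(root)))
    lab[lab > 0L] <- dense[lab[lab > 0L]]
  }
  # a cell must be able to hold a nucleus: objects below the nucleus area
  # floor are absorbed into the adjacent object sharing the longest boundary
  repeat {
    areas <- mask_areas(lab)
    small <- as.integer(names(areas)[areas < config$nucleus_min_area])
    merged_any <- FALSE
    for (id in small) {
      contact <- integer(0)
      for (sh in shifts) {
        nb <- .shift_mat(lab, sh[1], sh[2], pad = 0L)
        contact <- c(contact, nb[lab == id & nb > 0L & nb != id])
      }
      if (length(contact) > 0) {
        target <- as.integer(names(which.max(table(contact))))
        lab[lab == id] <- target
        merged_any <- TRUE
      }
    }
    if (!merged_any) break
  }
  labs <- mask_labels(lab)
  matrix(match(lab, c(0L, labs)) - 1L, nrow(lab))
}

# pixels 8-adjacent to a TRUE pixel of m (optionally counting the field edge)
.touches <- function(m, edge = FALSE) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- out | .shift_mat(m, dr, dc, pad = edge)
    }
  }
  out | m
}

# minimum pixel-center distance between every MN and every nucleus
.mn_nucleus_distances <- function(mn_mask, nucleus_mask) {
  h <- nrow(mn_mask)
  mn_ids <- mask_labels(mn_mask)
  nuc_ids <- mask_labels(nucleus_mask)
  D <- matrix(Inf, length(mn_ids), length(nuc_ids),
              dimnames = list(mn_ids, nuc_ids))
  if (length(mn_ids) == 0 || length(nuc_ids) == 0) return(D)
  coords <- function(mask, id) {
    idx <- which(mask == id)
    cbind(((idx - 1L) %% h) + 1L, ((idx - 1L) %/% h) + 1L)
  }
  nuc_px <- lapply(nuc_ids, function(id) coords(nucleus_mask, id))
  for (i in seq_along(mn_ids)) {
    mp <- coords(mn_mask, mn_ids[i])
    for (j in seq_along(nuc_ids)) {
      np <- nuc_px[[j]]
      d2 <- outer(mp[, 1], np[, 1], "-")^2 + outer(mp[, 2], np[, 2], "-")^2
      D[i, j] <- sqrt(min(d2))
    }
  }
  D
}

#' Integrate pixel-classifier and cell-classifier results
#'
#' Assigns every MN to the nucleus sharing its cell object; MN in a cell with
#' no nucleus, or outside all cells, fall back to nearest-nucleus assignment
#' (minimum mask-to-mask distance) within `config$mn_discard_radius` and are
#' dropped otherwise. If a reporter channel is supplied, each retained MN is
#' classified intact/ruptured by the reporter intensity ratio.
#'
#' @param nucleus_mask,mn_mask,cell_mask Label matrices of equal dimension.
#' @param image Optional [field_image()] for intensity features / rupture.
#' @param config An [mn_config()].
#' @return An object of class `mn_segmentation`: masks, `assignments`
#'   (data.frame mn_id / nucleus_id / distance / ruptured), per-nucleus
#'   `labels` and the object `table`.
#' @export
integrate_results <- function(nucleus_mask, mn_mask, cell_mask,
                              image = NULL, config = mn_config()) {
  stopifnot(identical(dim(nucleus_mask), dim(mn_mask)),
            identical(dim(nucleus_mask), dim(cell_mask)))
  mn_ids <- mask_labels(mn_mask)
  nuc_ids <- mask_labels(nucleus_mask)
  if (length(nuc_ids) == 0 && length(mn_ids) > 0) {
    warning("no nuclei found; dropping all ", length(mn_ids), " MN")
  }
  majority_cell <- function(mask, id) {
    v <- cell_mask[mask == id]
    v <- v[v > 0]
    if (length(v) == 0) return(0L)
    as.integer(names(which.max(table(v))))
  }
  nuc_cell <- vapply(nuc_ids, function(id) majority_cell(nucleus_mask, id), integer(1))
  D <- .mn_nucleus_distances(mn_mask, nucleus_mask)
  assign <- data.frame(mn_id = integer(0), nucleus_id = integer(0),
                       distance = numeric(0))
  dropped <- integer(0)
  for (i in seq_along(mn_ids)) {
    id <- mn_ids[i]
    target <- NA_integer_
    cell <- majority_cell(mn_mask, id)
    if (cell > 0 && any(nuc_cell == cell)) {
      cand <- which(nuc_cell == cell)
      target <- nuc_ids[cand[which.min(D[i, cand])]]
    } else if (length(nuc_ids) > 0) {
      j <- which.min(D[i, ])
      if (D[i, j] <= config$mn_discard_radius) target <- nuc_ids[j]
    }
    if (is.na(target)) {
      dropped <- c(dropped, id)
    } else {
      assign <- rbind(assign, data.frame(
        mn_id = id, nucleus_id = target,
        distance = D[i, match(target, nuc_ids)]))
    }
  }
  if (length(dropped) > 0) mn_mask[mn_mask %in% dropped] <- 0L

  assign$ruptured <- rep(NA, nrow(assign))
  if (!is.null(image) && "reporter" %in% names(image$channels) && nrow(assign) > 0) {
    rep_ch <- get_channel(image, "reporter")
    assign$ruptured <- vapply(seq_len(nrow(assign)), function(r) {
      classify_rupture(assign$mn_id[r], assign$nucleus_id[r], rep_ch,
                       mn_mask, nucleus_mask, config) == "ruptured"
    }, logical(1))
  }
  labels <- label_nuclei(nuc_ids, assign)
  tab <- measure_objects(list(nucleus = nucleus_mask, mn = mn_mask,
                              cell = cell_mask), image = image,
                         parents = assign)
  structure(list(nucleus_mask = nucleus_mask, mn_mask = mn_mask,
                 cell_mask = cell_mask, assignments = assign,
                 dropped_mn = dropped, labels = labels, table = tab),
            class = "mn_segmentation")
}

#' @export
print.mn_segmentation <- function(x, ...) {
  cat(sprintf("<mn_segmentation> %d nuclei, %d MN (%d dropped), %d cells\n",
              length(mask_labels(x$nucleus_mask)), nrow(x$assignments),
              length(x$dropped_mn), length(mask_labels(x$cell_mask))))
  invisible(x)
}

#' Object feature table
#'
#' Per labeled object: class, area, centroid, bounding box, solidity (area
#' over convex-hull area) and, when an image is supplied, per-channel mean and
#' maximum intensity.
#'
#' @param masks Named list of label matrices (e.g. `nucleus`, `mn`, `cell`).
#' @param image Optional [field_image()].
#' @param parents Optional assignment data.frame (`mn_id`, `nucleus_id`).
#' @return data.frame with one row per object.
#' @export
measure_objects <- function(masks, image = NULL, parents = NULL) {
  rows <- list()
  for (cls in names(masks)) {
    mask <- masks[[cls]]
    h <- nrow(mask)
    for (id in mask_labels(mask)) {
      idx <- which(mask == id)
      rr <- ((idx - 1L) %% h) + 1L
      cc <- ((idx - 1L) %/% h) + 1L
      hull <- convex_hull_pixels(rr, cc, dim(mask))
      row <- data.frame(class = cls, id = id, area = length(idx),
                        centroid_row = mean(rr), centroid_col = mean(cc),
                        bbox_rmin = min(rr), bbox_rmax = max(rr),
                        bbox_cmin = min(cc), bbox_cmax = max(cc),
                        solidity = length(idx) / length(hull),
                        parent = NA_integer_)
      if (cls == "mn" && !is.null(parents) && id %in% parents$mn_id) {
        row$parent <- parents$nucleus_id[match(id, parents$mn_id)]
      }
      if (!is.null(image)) {
        for (ch in names(image$channels)) {
          v <- image$channels[[ch]][idx]
          row[[paste0("mean_", ch)]] <- mean(v)
          row[[paste0("max_", ch)]] <- max(v)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0) {
    return(data.frame(class = character(0), id = integer(0), area = integer(0)))
  }
  do.call(rbind, rows)
}

#' Run the full tiled segmentation pipeline on a field
#'
#' Rescales to the working resolution if needed, predicts class probabilities
#' through the tiling + blending path, applies argmax binarization, small-
#' nucleus reclassification and convex-hull MN expansion, segments cells from
#' the predicted map set, and integrates everything into final labels.
#'
#' @param image A [field_image()] with a `chromatin` (and optionally
#'   `reporter`) channel.
#' @param pixel_model Pixel classifier backend (`mn_pixel_model`,
#'   `mn_ensemble`, or `mn_oracle_pixel`).
#' @param cell_model Cell-instance backend (`mn_cell_model` or
#'   `mn_oracle_maps`).
#' @param config An [mn_config()].
#' @param rescale_target Optional px/um target; required if the image
#'   resolution lies outside the working range.
#' @return An `mn_segmentation`.
#' @export
mnfinder_segment <- function(image, pixel_model, cell_model,
                             config = mn_config(), rescale_target = NULL) {
  wr <- config$working_resolution_range
  if (image$resolution < wr[1] || image$resolution > wr[2]) {
    if (is.null(rescale_target)) {
      stop(sprintf("image resolution %.3g px/um outside working range; supply rescale_target",
                   image$resolution), call. = FALSE)
    }
    image <- rescale_to_working(image, rescale_target, config)$image
  }
  chrom <- get_channel(image, "chromatin")
  probs <- predict_field_probs(pixel_model, chrom, config)
  cls <- apply_argmax(probs)
  nuc <- label_components(cls == 1L)
  mn <- label_components(cls == 2L)
  rc <- reclassify_small_nuclei(nuc, mn, config)
  mn <- expand_mn_to_hull(rc$mn_mask, rc$nucleus_mask)
  maps <- predict_map_set(cell_model, chrom, config)
  cells <- segment_cells(maps, config)
  integrate_results(rc$nucleus_mask, mn, cells, image = image, config = config)
}

#' Per-pixel argmax class from a probability array
#'
#' @param probs `H x W x K` probability array.
#' @return Integer matrix of classes `0..K-1`.
#' @export
apply_argmax <- function(probs) {
  d <- dim(probs)
  cls <- matrix(0L, d[1], d[2])
  best <- probs[, , 1]
  for (k in 2:d[3]) {
    better <- probs[, , k] > best
    cls[better] <- k - 1L
    best[better] <- probs[, , k][better]
  }
  cls
}
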