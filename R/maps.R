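#' Cell hulls grouping each nucleus with its micronuclei
#'
#' A "cell" is defined as the smallest convex shape enclosing a nucleus and its
#' associated MN; hulls are rasterized at pixel centers. A concave variant
#' (morphological closing of the member pixels with a disc of radius
#' `concavity`, followed by hole filling) is available for tightly packed
#' fields. When two hulls claim the same pixel, the pixel goes to the cell
#' whose nucleus centroid is nearer (ties to the lower cell id), so the
#' resulting hull masks partition the foreground.
#'
#' @param gt A [ground_truth()]; every MN must have a parent nucleus.
#' @param mode `"convex"` (default) or `"concave"`.
#' @param concavity Disc radius in pixels for the concave mode. Default 5.
#' @return An object of class `cell_hulls`: list with `dim` and `cells`, each
#'   cell a list of `cell_id`, `members` (nucleus + MN labels) and `idx`
#'   (linear pixel indices of the hull).
#' @export
make_cell_hulls <- function(gt, mode = c("convex", "concave"), concavity = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(gt, "ground_truth"))
  dimn <- dim(gt$nucleus_mask)
  nuc_ids <- mask_labels(gt$nucleus_mask)
  cents <- mask_centroids(gt$nucleus_mask)
  cells <- list()
  claim <- matrix(0L, dimn[1], dimn[2])
  for (i in seq_along(nuc_ids)) {
    nid <- nuc_ids[i]
    mn_ids <- as.integer(names(gt$mn_parent)[gt$mn_parent == nid])
    member_idx <- which(gt$nucleus_mask == nid |
                          (gt$mn_mask > 0 & gt$mn_mask %in% mn_ids))
    rows <- ((member_idx - 1L) %% dimn[1]) + 1L
    cols <- ((member_idx - 1L) %/% dimn[1]) + 1L
    hull_idx <- if (mode == "convex") {
      convex_hull_pixels(rows, cols, dimn)
    } else {
      m <- matrix(0, dimn[1], dimn[2])
      m[member_idx] <- 1
      br <- EBImage::makeBrush(2 * round(concavity) + 1, "disc")
      cl <- EBImage::fillHull(EBImage::closing(m, br))
      which(as.matrix(cl) > 0)
    }
    cells[[i]] <- list(cell_id = nid, members = c(nid, mn_ids), idx = hull_idx)
  }
  # resolve contested pixels to the nearer nucleus centroid
  if (length(cells) > 0) {
    counts <- matrix(0L, dimn[1], dimn[2])
    for (cl in cells) counts[cl$idx] <- counts[cl$idx] + 1L
    contested <- which(counts > 1L)
    if (length(contested) > 0) {
      rr <- ((contested - 1L) %% dimn[1]) + 1L
      cc <- ((contested - 1L) %/% dimn[1]) + 1L
      best <- rep(NA_integer_, length(contested))
      bestd <- rep(Inf, length(contested))
      for (i in seq_along(cells)) {
        inhull <- contested %in% cells[[i]]$idx
        d <- (rr - cents[i, "row"])^2 + (cc - cents[i, "col"])^2
        take <- inhull & (d < bestd)
        best[take] <- i
        bestd[take] <- d[take]
      }
      for (i in seq_along(cells)) {
        drop_idx <- contested[best != i]
        cells[[i]]$idx <- setdiff(cells[[i]]$idx, drop_idx)
      }
    }
  }
  structure(list(dim = dimn, cells = cells), class = "cell_hulls")
}

#' @export
print.cell_hulls <- function(x, ...) {
  cat(sprintf("<cell_hulls> %d cells on a %dx%d field\n",
              length(x$cells), x$dim[1], x$dim[2]))
  invisible(x)
}

#' Per-cell normalized distance map
#'
#' Inside each cell hull, the exact Euclidean distance to the nearest non-hull
#' pixel, divided by the cell's maximum so every non-empty cell attains exactly
#' 1; zero outside every hull.
#'
#' @param hulls A [make_cell_hulls()] result.
#' @param field_dim Optional output dimension (defaults to the hulls' field).
#' @return Numeric matrix in `[0, 1]`.
#' @export
make_distance_map <- function(hulls, field_dim = hulls$dim) {
  out <- matrix(0, field_dim[1], field_dim[2])
  for (cl in hulls$cells) {
    if (length(cl$idx) == 0) next
    cm <- matrix(TRUE, field_dim[1], field_dim[2])
    cm[cl$idx] <- FALSE  # targets: everything outside this cell's hull
    rows <- ((cl$idx - 1L) %% field_dim[1]) + 1L
    band <- sort(unique(rows))
    d <- edt_exact(cm, rows = band)
    v <- d[cl$idx]
    out[cl$idx] <- v / max(v)
  }
  out
}

#' Per-cell normalized proximity map
#'
#' For each cell, the exact Euclidean distance to the nearest pixel of any
#' *other* hull, masked to the cell's own hull, raised to the 4th power to
#' sharpen edges, and scaled to `[0, 1]` per cell. An isolated cell (no other
#' hull anywhere) has unbounded distances; they are capped at the field
#' diagonal, which after normalization yields a constant 1 inside the cell.
#' Values are low along shared borders with neighboring cells and rise towards
#' the far side of the cell.
#'
#' @inheritParams make_distance_map
#' @return Numeric matrix in `[0, 1]`.
#' @export
make_proximity_map <- function(hulls, field_dim = hulls$dim) {
  out <- matrix(0, field_dim[1], field_dim[2])
  n_cells <- length(hulls$cells)
  for (i in seq_len(n_cells)) {
    cl <- hulls$cells[[i]]
    if (length(cl$idx) == 0) next
    targets <- matrix(FALSE, field_dim[1], field_dim[2])
    for (j in seq_len(n_cells)) {
      if (j != i) targets[hulls$cells[[j]]$idx] <- TRUE
    }
    rows <- ((cl$idx - 1L) %% field_dim[1]) + 1L
    band <- sort(unique(rows))
    v <- if (!any(targets)) {
      rep(sqrt(sum(field_dim^2)), length(cl$idx))
    } else {
      d <- edt_exact(targets, rows = band)
      pmin(d[cl$idx], sqrt(sum(field_dim^2)))
    }
    v <- (v / max(v))^4
    out[cl$idx] <- v
  }
  out
}

#' Foreground, distance and proximity maps as one set
#'
#' @param hulls A [make_cell_hulls()] result.
#' @param field_dim Output dimension.
#' @return An object of class `mn_map_set`: list of `foreground`, `distance`,
#'   `proximity` matrices, each in `[0, 1]` and zero outside every hull.
#' @export
make_map_set <- function(hulls, field_dim = hulls$dim) {
  fg <- matrix(0, field_dim[1], field_dim[2])
  for (cl in hulls$cells) fg[cl$idx] <- 1
  structure(list(foreground = fg,
                 distance = make_distance_map(hulls, field_dim),
                 proximity = make_proximity_map(hulls, field_dim)),
            class = "mn_map_set")
}
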