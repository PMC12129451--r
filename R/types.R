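#' Multi-channel field image
#'
#' A `field_image` bundles one or more same-sized 2D intensity matrices with
#' the pixel resolution and the biological role of each channel. The chromatin
#' channel carries the DNA label (e.g. an H2B fusion or DAPI); the optional
#' reporter channel carries a nuclear-localized integrity reporter whose loss
#' from a micronucleus marks envelope rupture.
#'
#' @param channels Named list of numeric matrices, all of identical dimension,
#'   with non-negative intensities. Conventional names are `"chromatin"` and
#'   `"reporter"`.
#' @param resolution Pixel resolution in px/um; must be positive.
#' @return A `field_image` object.
#' @export
field_image <- function(channels, resolution) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("channels must be a non-empty named list of matrices", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all channels must be matrices of identical dimension", call. = FALSE)
  }
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1)))) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0) {
    stop("resolution must be a single positive number (px/um)", call. = FALSE)
  }
  structure(list(channels = channels, resolution = resolution),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<field_image> %dx%d px, %.3g px/um, channels: %s\n",
              d[1], d[2], x$resolution, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.field_image <- function(x) dim(x$channels[[1]])

#' Extract a channel matrix from a field image
#'
#' @param image A [field_image()].
#' @param role Channel name, e.g. `"chromatin"`.
#' @return The channel's intensity matrix.
#' @export
get_channel <- function(image, role) {
  stopifnot(inherits(image, "field_image"))
  if (!role %in% names(image$channels)) {
    stop("field has no '", role, "' channel", call. = FALSE)
  }
  image$channels[[role]]
}

#' Ground truth for one synthetic or annotated field
#'
#' Collects the instance-labeled nucleus and MN masks together with the true
#' MN-to-nucleus association and per-MN rupture status. Labels are positive
#' integers, 0 is background, and the two masks are pixel-disjoint.
#'
#' @param nucleus_mask,mn_mask Integer label matrices (0 = background).
#' @param mn_parent Named integer vector: for each MN label (name) the label of
#'   its parent nucleus.
#' @param mn_ruptured Named logical vector over the same MN labels.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(nucleus_mask, mn_mask, mn_parent = integer(0),
                         mn_ruptured = logical(0)) {
  stopifnot(identical(dim(nucleus_mask), dim(mn_mask)))
  if (any(nucleus_mask < 0) || any(mn_mask < 0)) {
    stop("instance labels must be non-negative", call. = FALSE)
  }
  if (any(nucleus_mask > 0 & mn_mask > 0)) {
    stop("nucleus and MN masks must be pixel-disjoint", call. = FALSE)
  }
  mn_ids <- mask_labels(mn_mask)
  mn_parent <- mn_parent[as.character(mn_ids)]
  mn_ruptured <- mn_ruptured[as.character(mn_ids)]
  if (length(mn_ids) > 0 && (anyNA(mn_parent) || anyNA(mn_ruptured))) {
    stop("every MN label needs a parent nucleus and a rupture flag", call. = FALSE)
  }
  if (length(mn_ids) > 0 &&
      !all(mn_parent %in% mask_labels(nucleus_mask))) {
    stop("MN parent labels must exist in the nucleus mask", call. = FALSE)
  }
  structure(list(nucleus_mask = nucleus_mask, mn_mask = mn_mask,
                 mn_parent = mn_parent, mn_ruptured = mn_ruptured),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d nuclei, %d MN (%d ruptured)\n",
              length(mask_labels(x$nucleus_mask)),
              length(mask_labels(x$mn_mask)),
              sum(x$mn_ruptured)))
  invisible(x)
}

#' Positive labels present in an instance mask
#'
#' @param mask Integer label matrix.
#' @return Sorted integer vector of the labels present (excluding background).
#' @export
mask_labels <- function(mask) {
  u <- sort(unique(as.integer(mask)))
  u[u > 0]
}

#' Areas of all labeled objects
#'
#' @param mask Integer label matrix.
#' @return Named integer vector of pixel counts per label.
#' @export
mask_areas <- function(mask) {
  v <- as.integer(mask)
  tab <- table(v[v > 0])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Centroids of all labeled objects
#'
#' @param mask Integer label matrix.
#' @return Matrix with one row per label and columns `label`, `row`, `col`.
#' @export
mask_centroids <- function(mask) {
  labs <- mask_labels(mask)
  if (length(labs) == 0) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("label", "row", "col"))))
  }
  idx <- which(mask > 0)
  lab <- mask[idx]
  rows <- ((idx - 1) %% nrow(mask)) + 1
  cols <- ((idx - 1) %/% nrow(mask)) + 1
  r <- tapply(rows, lab, mean)
  c_ <- tapply(cols, lab, mean)
  cbind(label = as.integer(names(r)), row = as.numeric(r), col = as.numeric(c_))
}

#' Per-nucleus classification labels
#'
#' A nucleus is MN+ iff it has at least one associated MN; an MN+ nucleus is
#' rupture+ iff at least one of its MN is ruptured, and rupture- if all of its
#' MN are intact. MN- nuclei carry no rupture status.
#'
#' @param nucleus_id Integer nucleus labels.
#' @param mn_status Character, `"MN+"` or `"MN-"` per nucleus.
#' @param rupture_status Character, `"rupture+"`, `"rupture-"` or `NA` per
#'   nucleus (`NA` iff MN-).
#' @param mn_ids List of integer vectors: the MN labels of each nucleus.
#' @return A data.frame of class `nucleus_labels`.
#' @export
nucleus_labels <- function(nucleus_id, mn_status, rupture_status, mn_ids) {
  stopifnot(length(nucleus_id) == length(mn_status),
            length(nucleus_id) == length(rupture_status),
            length(nucleus_id) == length(mn_ids))
  n_mn <- vapply(mn_ids, length, integer(1))
  if (any((mn_status == "MN+") != (n_mn >= 1))) {
    stop("mn_status must be MN+ iff the nucleus has associated MN", call. = FALSE)
  }
  if (any(is.na(rupture_status) != (mn_status == "MN-"))) {
    stop("rupture_status must be NA exactly for MN- nuclei", call. = FALSE)
  }
  out <- data.frame(nucleus_id = as.integer(nucleus_id),
                    mn_status = mn_status,
                    rupture_status = rupture_status,
                    n_mn = n_mn,
                    stringsAsFactors = FALSE)
  out$mn_ids <- mn_ids
  class(out) <- c("nucleus_labels", "data.frame")
  out
}
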