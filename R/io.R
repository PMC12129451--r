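# Disk I/O: multi-channel field TIFFs, 16-bit instance-label TIFFs, and
# ground-truth / object tables.

#' Write a field image as a multi-frame TIFF
#'
#' Channels are written as frames of a 16-bit TIFF; intensities are clipped to
#' `[0, 1]`. The resolution is not embedded; pass it explicitly when reading.
#'
#' @param image A [field_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(image, path) {
  stopifnot(inherits(image, "field_image"))
  d <- dim(image)
  arr <- array(0, c(d[1], d[2], length(image$channels)))
  for (i in seq_along(image$channels)) {
    arr[, , i] <- pmin(pmax(image$channels[[i]], 0), 1)
  }
  EBImage::writeImage(EBImage::Image(arr), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' Read a field image from a TIFF
#'
#' @param path TIFF path.
#' @param resolution Pixel resolution in px/um (required; never guessed).
#' @param channel_names Names for the frames, in order.
#' @return A [field_image()].
#' @export
read_field_tiff <- function(path, resolution,
                            channel_names = c("chromatin", "reporter")) {
  img <- EBImage::readImage(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  n <- dim(a)[3]
  chans <- lapply(seq_len(n), function(i) a[, , i])
  names(chans) <- channel_names[seq_len(n)]
  field_image(chans, resolution)
}

#' Write an instance-label mask as a 16-bit TIFF
#'
#' Labels are stored as `label / 65535` gray values; [read_mask_tiff()]
#' reverses the scaling exactly for labels up to 65535.
#'
#' @param mask Integer label matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(max(mask) <= 65535)
  EBImage::writeImage(EBImage::Image(mask / 65535), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- as.matrix(EBImage::readImage(path))
  matrix(as.integer(round(m * 65535)), nrow(m))
}

#' Ground truth as a flat table
#'
#' One row per object (nucleus or MN): id, class, parent id, rupture flag,
#' centroid and area; the on-disk companion of the label TIFFs.
#'
#' @param gt A [ground_truth()].
#' @return data.frame.
#' @export
ground_truth_table <- function(gt) {
  rows <- list()
  cent_n <- mask_centroids(gt$nucleus_mask)
  area_n <- mask_areas(gt$nucleus_mask)
  for (id in mask_labels(gt$nucleus_mask)) {
    i <- match(id, cent_n[, "label"])
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, class = "nucleus", parent = NA_integer_, ruptured = NA,
      centroid_row = cent_n[i, "row"], centroid_col = cent_n[i, "col"],
      area = area_n[[as.character(id)]])
  }
  cent_m <- mask_centroids(gt$mn_mask)
  area_m <- mask_areas(gt$mn_mask)
  for (id in mask_labels(gt$mn_mask)) {
    i <- match(id, cent_m[, "label"])
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, class = "mn", parent = gt$mn_parent[[as.character(id)]],
      ruptured = gt$mn_ruptured[[as.character(id)]],
      centroid_row = cent_m[i, "row"], centroid_col = cent_m[i, "col"],
      area = area_m[[as.character(id)]])
  }
  if (length(rows) == 0) {
    return(data.frame(id = integer(0), class = character(0),
                      parent = integer(0), ruptured = logical(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      area = integer(0)))
  }
  do.call(rbind, rows)
}
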