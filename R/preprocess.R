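#' Rescale an image to a working resolution
#'
#' Linearly (bilinearly) rescales a field so that its pixel resolution equals
#' `target` px/um. The tiled segmenter operates at 1.55-2.8 px/um (nuclei
#' around 30 px in diameter); images acquired at other resolutions must be
#' brought into that range first. Instance masks passed alongside are rescaled
#' with nearest-neighbour interpolation so labels stay integral.
#'
#' @param image A [field_image()].
#' @param target Target resolution in px/um; must lie inside
#'   `config$working_resolution_range`.
#' @param config An [mn_config()].
#' @param masks Optional named list of label matrices rescaled alongside.
#' @return A list with `image` (rescaled [field_image()]) and `masks`.
#' @export
rescale_to_working <- function(image, target, config = mn_config(), masks = NULL) {
  stopifnot(inherits(image, "field_image"))
  wr <- config$working_resolution_range
  if (target < wr[1] || target > wr[2]) {
    stop(sprintf("target resolution %.3g px/um outside working range [%.3g, %.3g]",
                 target, wr[1], wr[2]), call. = FALSE)
  }
  if (identical(target, image$resolution) || target == image$resolution) {
    return(list(image = image, masks = masks))
  }
  f <- target / image$resolution
  d <- dim(image)
  nd <- pmax(round(d * f), 1L)
  rs <- function(m, filter) {
    matrix(EBImage::resize(EBImage::Image(m), w = nd[1], h = nd[2],
                           filter = filter), nd[1], nd[2])
  }
  channels <- lapply(image$channels, function(ch) pmax(rs(ch, "bilinear"), 0))
  out_masks <- if (!is.null(masks)) {
    lapply(masks, function(m) {
      mm <- rs(m, "none")
      storage.mode(mm) <- "integer"
      mm
    })
  } else NULL
  list(image = field_image(channels, target), masks = out_masks)
}

# 3x3 Sobel gradients with replicate boundary handling
.sobel_xy <- function(x) {
  h <- nrow(x); w <- ncol(x)
  sh <- function(dr, dc) {
    x[pmin(pmax(seq_len(h) + dr, 1L), h), pmin(pmax(seq_len(w) + dc, 1L), w),
      drop = FALSE]
  }
  gx <- (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1)) -
        (sh(-1,  1) + 2 * sh(0,  1) + sh(1,  1))
  gy <- (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1)) -
        (sh( 1, -1) + 2 * sh( 1, 0) + sh( 1, 1))
  list(gx = gx, gy = gy)
}

#' Sobel edge-magnitude channel
#'
#' Computes the 3x3 Sobel gradient magnitude of a single-channel image. The
#' input is min-max normalized first, so edge magnitudes are comparable across
#' exposure settings, and the magnitude is then rescaled back to the input's
#' value range. A constant image yields an all-zero edge channel.
#'
#' @param x Numeric matrix.
#' @return Numeric matrix of the same size.
#' @export
sobel_magnitude <- function(x) {
  rng <- range(x)
  span <- rng[2] - rng[1]
  if (span == 0) return(matrix(0, nrow(x), ncol(x)))
  g <- .sobel_xy((x - rng[1]) / span)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mx <- max(mag)
  if (mx > 0) mag <- mag / mx * span
  mag
}

#' Expand a single-channel image into the two-channel network input
#'
#' Channel 1 is the raw image, channel 2 its Sobel edge magnitude
#' ([sobel_magnitude()]).
#'
#' @param x Numeric matrix.
#' @return Array of dimension `c(nrow, ncol, 2)`.
#' @export
add_sobel_channel <- function(x) {
  stopifnot(is.matrix(x))
  array(c(x, sobel_magnitude(x)), dim = c(nrow(x), ncol(x), 2L))
}

#' Sliding-window tile origins
#'
#' Origins advance by `stride` along each axis; a final row/column of tiles is
#' clamped to end exactly at the field edge so every pixel is covered by real
#' pixels (no reflection or padding of interior fields).
#'
#' @param field_dim Integer length-2 field dimension.
#' @param size Tile side in pixels.
#' @param stride Window advance in pixels.
#' @return Integer matrix with columns `row`, `col` of 1-based tile origins in
#'   row-major order.
#' @export
tile_field_origins <- function(field_dim, size, stride) {
  ax <- function(n) {
    if (n <= size) return(1L)
    o <- seq(1L, n - size + 1L, by = stride)
    if (o[length(o)] + size - 1L < n) o <- c(o, n - size + 1L)
    o
  }
  or <- ax(field_dim[1]); oc <- ax(field_dim[2])
  out <- cbind(row = rep(or, each = length(oc)), col = rep(oc, times = length(or)))
  storage.mode(out) <- "integer"
  out
}

#' Cut a field into overlapping two-channel tiles
#'
#' Fields smaller than the tile size are zero-padded symmetrically first.
#' Tiling is deterministic and independent of image content.
#'
#' @param x Single-channel matrix (chromatin) or an `nrow x ncol x 2` array
#'   that already carries the Sobel channel.
#' @param config An [mn_config()]; supplies `tile_size` and `tile_stride`.
#' @return List of tiles, each `list(data = size x size x 2 array,
#'   origin = c(row, col))`, plus attributes `field_dim` (padded dimension) and
#'   `pad` (top/left padding applied).
#' @export
tile_field <- function(x, config = mn_config()) {
  if (is.matrix(x)) x <- add_sobel_channel(x)
  stopifnot(length(dim(x)) == 3L)
  ts <- config$tile_size
  d <- dim(x)[1:2]
  pad <- c(0L, 0L)
  if (any(d < ts)) {
    nd <- pmax(d, ts)
    pad <- (nd - d) %/% 2L
    xp <- array(0, dim = c(nd, dim(x)[3]))
    xp[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), ] <- x
    x <- xp
    d <- nd
  }
  origins <- tile_field_origins(d, ts, config$tile_stride)
  tiles <- lapply(seq_len(nrow(origins)), function(i) {
    r <- origins[i, 1]; c_ <- origins[i, 2]
    list(data = x[r:(r + ts - 1L), c_:(c_ + ts - 1L), , drop = FALSE],
         origin = c(r, c_))
  })
  attr(tiles, "field_dim") <- d
  attr(tiles, "pad") <- pad
  tiles
}

# per-axis triangular blending profile: ramps linearly over the overlap width
.blend_profile <- function(size, stride) {
  w <- size - stride
  if (w <= 0) return(rep(1, size))
  i <- seq_len(size)
  pmin(pmin(i, size + 1 - i), w) / w
}

#' Reassemble per-tile predictions into a field by linear blending
#'
#' Each tile contributes with a weight that ramps linearly from the tile edge
#' towards its interior (the product of per-axis triangular profiles over the
#' overlap width); weights are normalized to sum to one at every pixel, so
#' constant agreeing tiles reproduce their value exactly.
#'
#' @param tiles List of `list(origin = c(row, col), pred = matrix or H x W x C
#'   array)` tile predictions (values in `[0, 1]`).
#' @param field_dim Integer length-2 output dimension.
#' @param config An [mn_config()].
#' @return Matrix (single channel) or array of blended predictions.
#' @export
blend_tiles <- function(tiles, field_dim, config = mn_config()) {
  stopifnot(length(tiles) > 0)
  p1 <- tiles[[1]]$pred
  nc <- if (length(dim(p1)) == 3L) dim(p1)[3] else 1L
  ts <- if (!is.null(dim(p1))) dim(p1)[1] else stop("tile predictions need dims")
  prof <- .blend_profile(ts, config$tile_stride)
  w2d <- outer(prof, prof)
  acc <- array(0, dim = c(field_dim, nc))
  wsum <- matrix(0, field_dim[1], field_dim[2])
  for (t_ in tiles) {
    r <- t_$origin[1]; c_ <- t_$origin[2]
    rows <- r:(r + ts - 1L); cols <- c_:(c_ + ts - 1L)
    pred <- t_$pred
    if (length(dim(pred)) == 2L) dim(pred) <- c(dim(pred), 1L)
    for (k in seq_len(nc)) {
      acc[rows, cols, k] <- acc[rows, cols, k] + pred[, , k] * w2d
    }
    wsum[rows, cols] <- wsum[rows, cols] + w2d
  }
  if (any(wsum == 0)) stop("tiles do not cover the field", call. = FALSE)
  for (k in seq_len(nc)) acc[, , k] <- acc[, , k] / wsum
  if (nc == 1L) acc[, , 1] else acc
}

# bilinear resize of a matrix to a square side s
.resize_bilinear <- function(m, s) {
  matrix(EBImage::resize(EBImage::Image(m), w = s, h = s, filter = "bilinear"),
         s, s)
}

.resize_nearest <- function(m, s) {
  matrix(EBImage::resize(EBImage::Image(m), w = s, h = s, filter = "none"),
         s, s)
}

#' Build the three-channel nucleus-centered crop for the rapid classifier
#'
#' Cuts a `vcs_crop_size` window centered on the nucleus centroid (clamped to
#' stay inside the field), applies Sobel edge detection at the native crop
#' scale, linearly enlarges to `vcs_net_input_size`, and stacks chromatin, a
#' duplicate of the chromatin channel, and the Sobel result.
#'
#' @param image A [field_image()] (chromatin channel used) or a matrix.
#' @param nucleus_mask Integer label matrix.
#' @param label Nucleus label to center on.
#' @param config An [mn_config()].
#' @return List with `data` (net input array, e.g. 96 x 96 x 3) and `window`
#'   (`c(row0, col0, size)` of the native crop in field coordinates).
#' @export
make_vcs_crop <- function(image, nucleus_mask, label, config = mn_config()) {
  chrom <- if (inherits(image, "field_image")) get_channel(image, "chromatin") else image
  idx <- which(nucleus_mask == label)
  if (length(idx) == 0) stop("nucleus label ", label, " not found", call. = FALSE)
  h <- nrow(chrom); w <- ncol(chrom)
  cr <- mean(((idx - 1) %% h) + 1)
  cc <- mean(((idx - 1) %/% h) + 1)
  s <- config$vcs_crop_size
  r0 <- min(max(floor(cr + 0.5) - s %/% 2L + 1L, 1L), max(h - s + 1L, 1L))
  c0 <- min(max(floor(cc + 0.5) - s %/% 2L + 1L, 1L), max(w - s + 1L, 1L))
  crop <- matrix(0, s, s)
  rows <- r0:min(r0 + s - 1L, h); cols <- c0:min(c0 + s - 1L, w)
  crop[seq_along(rows), seq_along(cols)] <- chrom[rows, cols]
  sob <- sobel_magnitude(crop)
  ns <- config$vcs_net_input_size
  big <- .resize_bilinear(crop, ns)
  big_sob <- .resize_bilinear(sob, ns)
  list(data = array(c(big, big, big_sob), dim = c(ns, ns, 3L)),
       window = c(row0 = r0, col0 = c0, size = s))
}
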