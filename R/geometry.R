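# Exact Euclidean distance transforms, morphological thinning and convex-hull
# rasterization. The EDT is the Felzenszwalb-Huttenlocher separable algorithm
# (exact squared distances; column pass vectorized, row pass restrictable to a
# band of rows so per-cell maps only pay for their bounding box).

.EDT_BIG <- 1e12

# lower-envelope 1D squared-distance transform of a cost vector f
.dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  if (n > 1L) {
    for (q in 2:n) {
      repeat {
        vk <- v[k]
        s <- ((f[q] + q * q) - (f[vk] + vk * vk)) / (2 * q - 2 * vk)
        if (s <= z[k] && k > 1L) k <- k - 1L else break
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Exact Euclidean distance to a target set
#'
#' For every pixel, the exact Euclidean distance to the nearest `TRUE` pixel of
#' `target`. Pixels with no reachable target (empty target set) get `Inf`.
#'
#' @param target Logical matrix of target pixels.
#' @param rows Optional integer vector; only these rows of the result are
#'   computed (others return `NA`), which makes masked per-cell maps cheap.
#' @return Numeric matrix of distances.
#' @export
edt_exact <- function(target, rows = NULL) {
  h <- nrow(target); w <- ncol(target)
  # vertical pass: per-column distance (in rows) to nearest target, squared
  dcol <- matrix(.EDT_BIG, h, w)
  dcol[target] <- 0
  if (h > 1L) {
    for (r in 2:h) dcol[r, ] <- pmin(dcol[r, ], (sqrt(dcol[r - 1L, ]) + 1)^2)
    for (r in (h - 1L):1L) dcol[r, ] <- pmin(dcol[r, ], (sqrt(dcol[r + 1L, ]) + 1)^2)
  }
  if (is.null(rows)) rows <- seq_len(h)
  out <- matrix(NA_real_, h, w)
  for (r in rows) {
    out[r, ] <- .dt1d(dcol[r, ])
  }
  out <- sqrt(out)
  out[out >= sqrt(.EDT_BIG) / 2] <- Inf
  out
}

# 8-neighbour shift helper: value of m offset by (dr, dc), edge-padded with pad
.shift_mat <- function(m, dr, dc, pad = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(pad, h, w)
  rs <- max(1, 1 - dr):min(h, h - dr)
  cs <- max(1, 1 - dc):min(w, w - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Morphological skeleton by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels of a binary mask until only a one-pixel
#' wide, 8-connected skeleton remains.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- mask * 1L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- .shift_mat(m, -1L, 0L);  p3 <- .shift_mat(m, -1L, 1L)
      p4 <- .shift_mat(m, 0L, 1L);   p5 <- .shift_mat(m, 1L, 1L)
      p6 <- .shift_mat(m, 1L, 0L);   p7 <- .shift_mat(m, 1L, -1L)
      p8 <- .shift_mat(m, 0L, -1L);  p9 <- .shift_mat(m, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- m == 1 & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Rasterized filled convex hull of a pixel set. rows/cols are 1-based pixel
# coordinates; returns linear indices into a matrix of dimension dimn. A pixel
# belongs to the hull iff its center is inside or on the hull polygon of the
# input pixel centers (integer cross-product test, so the result is exact).
convex_hull_pixels <- function(rows, cols, dimn) {
  stopifnot(length(rows) == length(cols))
  if (length(rows) == 0) return(integer(0))
  pts <- unique(cbind(rows, cols))
  if (nrow(pts) <= 2) return((cols - 1L) * dimn[1] + rows)
  hidx <- grDevices::chull(pts[, 1], pts[, 2])
  vr <- pts[hidx, 1]; vc <- pts[hidx, 2]
  nv <- length(vr)
  if (nv <= 2) return((cols - 1L) * dimn[1] + rows)
  # orientation from the signed area; then inside = all cross products >= 0
  area2 <- sum(vr * vc[c(2:nv, 1)] - vr[c(2:nv, 1)] * vc)
  if (area2 < 0) { vr <- rev(vr); vc <- rev(vc) }
  rb <- min(rows):max(rows)
  cb <- min(cols):max(cols)
  pr <- rep(rb, times = length(cb))
  pc <- rep(cb, each = length(rb))
  inside <- rep(TRUE, length(pr))
  for (e in seq_len(nv)) {
    e2 <- if (e == nv) 1L else e + 1L
    cr <- (vr[e2] - vr[e]) * (pc - vc[e]) - (vc[e2] - vc[e]) * (pr - vr[e])
    inside <- inside & cr >= 0
    if (!any(inside)) break
  }
  (pc[inside] - 1L) * dimn[1] + pr[inside]
}

# filled convex hull of all positive pixels of a binary/label mask
convex_hull_mask <- function(mask) {
  idx <- which(mask > 0)
  h <- nrow(mask)
  out <- matrix(FALSE, h, ncol(mask))
  if (length(idx) == 0) return(out)
  out[convex_hull_pixels(((idx - 1L) %% h) + 1L, ((idx - 1L) %/% h) + 1L,
                         dim(mask))] <- TRUE
  out
}

#' 8-connected component labeling
#'
#' Connected components of a binary mask under 8-connectivity (diagonal
#' contacts join), the standard convention for blob labeling in this domain.
#'
#' @param bin Logical or 0/1 matrix.
#' @return Integer label matrix, labels 1..n, 0 = background.
#' @export
label_components <- function(bin) {
  lab <- matrix(as.integer(EBImage::bwlabel(bin > 0)), nrow(bin))
  n_lab <- max(lab)
  if (n_lab <= 1L) return(lab)
  # merge 4-connected labels that touch diagonally
  parent <- seq_len(n_lab)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (sh in list(c(-1L, -1L), c(-1L, 1L))) {
    nb <- .shift_mat(lab, sh[1], sh[2], pad = 0L)
    sel <- which(lab > 0L & nb > 0L & lab != nb)
    if (length(sel) == 0) next
    pr <- unique(cbind(lab[sel], nb[sel]))
    for (r in seq_len(nrow(pr))) {
      ra <- find(pr[r, 1]); rb <- find(pr[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n_lab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}
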