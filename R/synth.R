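#' Synthetic-field generator configuration
#'
#' Parameters of the two-channel synthetic fluorescence field generator. The
#' generator emulates widefield images of chromatin-labeled cells carrying a
#' nuclear-localized integrity reporter: elliptical, optionally lobulated
#' nuclei of ~30 px diameter, micronuclei (MN) placed close to their parent
#' nucleus with a lognormal area distribution whose median is calibrated to
#' 34 px at the working resolution, ruptured MN with reporter signal far below
#' the rupture ratio and intact MN far above it, plus the classic distractor
#' objects (nuclear blebs, chromatin bridges, dim debris) and Gaussian read
#' noise over a uniform background.
#'
#' @param field_size Side of the square field in pixels. Default 256.
#' @param n_cells Number of nuclei to place. Default 8.
#' @param resolution Simulated pixel resolution in px/um. Default 2.
#' @param mn_frequency Fraction of cells carrying at least one MN. Default 0.6.
#' @param mn_per_cell Probabilities of 1, 2, 3 MN for an MN+ cell.
#' @param mn_area_meanlog,mn_area_sdlog Lognormal parameters of the MN pixel
#'   area; the default median is `exp(mn_area_meanlog)` = 34 px.
#' @param mn_area_range Hard clamp on sampled MN areas in pixels.
#' @param rupture_fraction Fraction of MN drawn ruptured. Default 0.4.
#' @param parent_proximity_factor Required ratio between the distance to the
#'   nearest non-parent nucleus and the distance to the parent; placements are
#'   retried until the ratio is met or retries are exhausted. Default 3.3.
#' @param nucleus_semiaxes_a,nucleus_semiaxes_b Ranges of the nucleus ellipse
#'   semi-axes in pixels.
#' @param lobulation_amplitude Relative amplitude of the sinusoidal boundary
#'   perturbation emulating lobulated nuclei (0 disables). Default 0.08.
#' @param bleb_rate,bridge_rate Per-cell probabilities of a nuclear bleb and of
#'   a chromatin bridge to a neighboring nucleus.
#' @param debris_count Expected number of dim debris specks per field.
#' @param background Uniform background intensity (arbitrary units in [0,1]).
#' @param noise_sd Standard deviation of Gaussian read noise.
#' @param intact_ratio_range Reporter MN/nucleus amplitude ratio range for
#'   intact MN; must lie above the rupture threshold with margin.
#' @param ruptured_ratio_range Same for ruptured MN; below threshold.
#' @param blur_sigma Gaussian optical blur applied before noise. Default 0.5.
#' @param max_retries Placement retries before giving up. Default 200.
#' @param seed Integer seed fixing all randomness.
#' @return A `synth_config` object.
#' @export
synth_config <- function(field_size = 256L,
                         n_cells = 8L,
                         resolution = 2,
                         mn_frequency = 0.6,
                         mn_per_cell = c(0.7, 0.2, 0.1),
                         mn_area_meanlog = log(34),
                         mn_area_sdlog = 0.5,
                         mn_area_range = c(6, 150),
                         rupture_fraction = 0.4,
                         parent_proximity_factor = 3.3,
                         nucleus_semiaxes_a = c(12, 17),
                         nucleus_semiaxes_b = c(10, 14),
                         lobulation_amplitude = 0.08,
                         bleb_rate = 0.15,
                         bridge_rate = 0.1,
                         debris_count = 3,
                         background = 0.02,
                         noise_sd = 0.005,
                         intact_ratio_range = c(0.30, 0.90),
                         ruptured_ratio_range = c(0.005, 0.05),
                         blur_sigma = 0.5,
                         max_retries = 200L,
                         seed = 1L) {
  sc <- list(field_size = as.integer(field_size), n_cells = as.integer(n_cells),
             resolution = resolution, mn_frequency = mn_frequency,
             mn_per_cell = mn_per_cell / sum(mn_per_cell),
             mn_area_meanlog = mn_area_meanlog, mn_area_sdlog = mn_area_sdlog,
             mn_area_range = mn_area_range,
             rupture_fraction = rupture_fraction,
             parent_proximity_factor = parent_proximity_factor,
             nucleus_semiaxes_a = nucleus_semiaxes_a,
             nucleus_semiaxes_b = nucleus_semiaxes_b,
             lobulation_amplitude = lobulation_amplitude,
             bleb_rate = bleb_rate, bridge_rate = bridge_rate,
             debris_count = debris_count, background = background,
             noise_sd = noise_sd,
             intact_ratio_range = intact_ratio_range,
             ruptured_ratio_range = ruptured_ratio_range,
             blur_sigma = blur_sigma, max_retries = as.integer(max_retries),
             seed = as.integer(seed))
  fracs <- c(sc$mn_frequency, sc$rupture_fraction, sc$bleb_rate, sc$bridge_rate)
  if (any(fracs < 0 | fracs > 1)) {
    stop("mn_frequency, rupture_fraction, bleb_rate, bridge_rate must be in [0,1]",
         call. = FALSE)
  }
  if (sc$field_size < 64L) stop("field_size must be at least 64", call. = FALSE)
  if (any(sc$mn_area_range <= 0) || sc$mn_area_sdlog < 0) {
    stop("MN area distribution must yield positive areas", call. = FALSE)
  }
  class(sc) <- "synth_config"
  sc
}

# Rasterize an ellipse with optional sinusoidal boundary lobulation.
# Returns integer matrix indices (pixel linear indices) within a field of the
# given dimension.
.raster_blob <- function(dimn, center, a, b, theta, lobulation = 0, lobes = 0,
                         phase = 0) {
  rmax <- max(a, b) * (1 + lobulation) + 1
  rows <- max(1, floor(center[1] - rmax)):min(dimn[1], ceiling(center[1] + rmax))
  cols <- max(1, floor(center[2] - rmax)):min(dimn[2], ceiling(center[2] + rmax))
  if (length(rows) == 0 || length(cols) == 0) return(integer(0))
  dr <- rep(rows - center[1], times = length(cols))
  dc <- rep(cols - center[2], each = length(rows))
  # rotate into the ellipse frame
  x <- dr * cos(theta) + dc * sin(theta)
  y <- -dr * sin(theta) + dc * cos(theta)
  rho <- sqrt((x / a)^2 + (y / b)^2)
  lim <- 1
  if (lobulation > 0 && lobes > 0) {
    phi <- atan2(y, x)
    lim <- 1 + lobulation * sin(lobes * phi + phase)
  }
  keep <- rho <= lim
  rr <- rep(rows, times = length(cols))[keep]
  cc <- rep(cols, each = length(rows))[keep]
  (cc - 1L) * dimn[1] + rr
}

# boundary radius of the (unlobulated) ellipse along field-frame direction ang
.ellipse_radius <- function(a, b, theta, ang) {
  ca <- cos(ang - theta); sa <- sin(ang - theta)
  1 / sqrt((ca / a)^2 + (sa / b)^2)
}

#' Generate one synthetic two-channel field with full ground truth
#'
#' Draws nuclei, micronuclei, distractors and noise according to a
#' [synth_config()] and returns both the rendered image and the exact ground
#' truth (instance masks, MN-to-nucleus association, rupture flags). Fully
#' deterministic under the config seed.
#'
#' @param synth A [synth_config()].
#' @return A list with elements `image` (a [field_image()] with `chromatin` and
#'   `reporter` channels) and `gt` (a [ground_truth()]).
#' @examples
#' f <- generate_field(synth_config(n_cells = 4, seed = 7))
#' f$gt
#' @export
generate_field <- function(synth) {
  stopifnot(inherits(synth, "synth_config"))
  set.seed(synth$seed)
  n <- synth$field_size
  dimn <- c(n, n)
  nuc_mask <- matrix(0L, n, n)
  mn_mask <- matrix(0L, n, n)
  chrom <- matrix(0, n, n)
  rep_ch <- matrix(0, n, n)
  occupied <- matrix(FALSE, n, n)

  margin <- 22
  nuclei <- list()
  for (i in seq_len(synth$n_cells)) {
    placed <- FALSE
    for (try in seq_len(synth$max_retries)) {
      a <- stats::runif(1, synth$nucleus_semiaxes_a[1], synth$nucleus_semiaxes_a[2])
      b <- stats::runif(1, synth$nucleus_semiaxes_b[1], synth$nucleus_semiaxes_b[2])
      theta <- stats::runif(1, 0, pi)
      ctr <- stats::runif(2, margin, n - margin)
      ok <- TRUE
      for (nu in nuclei) {
        if (sqrt(sum((ctr - nu$center)^2)) < (max(a, b) + nu$rmax + 8)) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      lobes <- if (synth$lobulation_amplitude > 0) sample(3:6, 1) else 0
      idx <- .raster_blob(dimn, ctr, a, b, theta,
                          lobulation = synth$lobulation_amplitude,
                          lobes = lobes, phase = stats::runif(1, 0, 2 * pi))
      if (length(idx) == 0 || any(occupied[idx])) next
      amp_c <- stats::runif(1, 0.65, 0.9)
      amp_r <- 0.8 * stats::runif(1, 0.9, 1.1)
      nuc_mask[idx] <- i
      chrom[idx] <- amp_c
      rep_ch[idx] <- amp_r
      occupied[idx] <- TRUE
      nuclei[[i]] <- list(center = ctr, a = a, b = b, theta = theta,
                          rmax = max(a, b) * (1 + synth$lobulation_amplitude),
                          amp_c = amp_c, amp_r = amp_r)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place ", synth$n_cells, " nuclei without overlap; ",
           "increase field_size or max_retries", call. = FALSE)
    }
  }
  n_placed <- length(nuclei)

  # dilate occupancy by a 2 px guard so objects never touch
  if (n_placed > 0) {
    guard <- EBImage::dilate(occupied * 1, EBImage::makeBrush(5, "disc")) > 0
  } else {
    guard <- occupied
  }

  mn_parent <- integer(0)
  mn_ruptured <- logical(0)
  mn_guard <- matrix(FALSE, n, n)
  mn_next <- 0L
  if (n_placed > 0 && synth$mn_frequency > 0) {
    has_mn <- stats::runif(n_placed) < synth$mn_frequency
    for (i in which(has_mn)) {
      nu <- nuclei[[i]]
      k <- sample(seq_along(synth$mn_per_cell), 1, prob = synth$mn_per_cell)
      for (m in seq_len(k)) {
        for (try in seq_len(synth$max_retries)) {
          area <- stats::rlnorm(1, synth$mn_area_meanlog, synth$mn_area_sdlog)
          area <- min(max(area, synth$mn_area_range[1]), synth$mn_area_range[2])
          r0 <- sqrt(area / pi)
          u <- stats::runif(1, 1, 1.25)
          ma <- r0 * u; mb <- r0 / u
          mtheta <- stats::runif(1, 0, pi)
          ang <- stats::runif(1, 0, 2 * pi)
          gap <- stats::runif(1, 2, 10)
          rb <- .ellipse_radius(nu$a, nu$b, nu$theta, ang) *
            (1 + synth$lobulation_amplitude)
          d_parent <- gap + max(ma, mb)
          ctr <- nu$center + (rb + d_parent) * c(cos(ang), sin(ang))
          if (any(ctr < 3) || any(ctr > n - 2)) next
          # parent-proximity condition against other nuclei (boundary approx.)
          ok_prox <- TRUE
          for (j in seq_len(n_placed)) {
            if (j == i) next
            d_other <- sqrt(sum((ctr - nuclei[[j]]$center)^2)) - nuclei[[j]]$rmax
            if (d_other < synth$parent_proximity_factor * gap) {
              ok_prox <- FALSE; break
            }
          }
          if (!ok_prox && try < synth$max_retries / 2) next
          idx <- .raster_blob(dimn, ctr, ma, mb, mtheta)
          if (length(idx) == 0 || any(guard[idx])) next
          mn_next <- mn_next + 1L
          ruptured <- stats::runif(1) < synth$rupture_fraction
          ratio <- if (ruptured) {
            stats::runif(1, synth$ruptured_ratio_range[1], synth$ruptured_ratio_range[2])
          } else {
            stats::runif(1, synth$intact_ratio_range[1], synth$intact_ratio_range[2])
          }
          mn_mask[idx] <- mn_next
          chrom[idx] <- nu$amp_c * stats::runif(1, 0.85, 1.1)
          rep_ch[idx] <- nu$amp_r * ratio
          occupied[idx] <- TRUE
          # extend the guard by a 2 px ring around the new MN
          rr <- ((idx - 1) %% n) + 1; cc <- ((idx - 1) %/% n) + 1
          for (dr in -2:2) for (dc in -2:2) {
            r2 <- rr + dr; c2 <- cc + dc
            keep <- r2 >= 1 & r2 <= n & c2 >= 1 & c2 <= n
            lin <- (c2[keep] - 1L) * n + r2[keep]
            guard[lin] <- TRUE
            mn_guard[lin] <- TRUE
          }
          mn_parent[as.character(mn_next)] <- i
          mn_ruptured[as.character(mn_next)] <- ruptured
          break
        }
      }
    }
  }

  # distractors: blebs (protrusions contiguous with the nucleus), chromatin
  # bridges (thin curves between two nuclei), dim debris; the first two are
  # nucleus-class pixels and never enter the MN ground truth
  for (i in seq_len(n_placed)) {
    if (stats::runif(1) < synth$bleb_rate) {
      nu <- nuclei[[i]]
      ang <- stats::runif(1, 0, 2 * pi)
      rb <- .ellipse_radius(nu$a, nu$b, nu$theta, ang)
      br <- stats::runif(1, 2.5, 4.5)
      ctr <- nu$center + (rb + br * 0.3) * c(cos(ang), sin(ang))
      idx <- .raster_blob(dimn, ctr, br, br, 0)
      free <- idx[nuc_mask[idx] == 0]
      # a bleb must stay contiguous with its own nucleus (lobulation can pull
      # the true boundary inward of the unperturbed ellipse) and may only
      # claim background pixels away from MN and other nuclei
      if (length(idx) > 0 && any(nuc_mask[idx] == i) &&
          all(nuc_mask[idx] %in% c(0L, i)) &&
          all(mn_mask[idx] == 0) && !any(mn_guard[free])) {
        nuc_mask[idx] <- i
        chrom[idx] <- nu$amp_c
        rep_ch[idx] <- nu$amp_r
        occupied[idx] <- TRUE
      }
    }
  }
  if (n_placed >= 2) {
    for (i in seq_len(n_placed)) {
      if (stats::runif(1) < synth$bridge_rate) {
        dists <- vapply(nuclei, function(nu) sqrt(sum((nu$center - nuclei[[i]]$center)^2)),
                        numeric(1))
        dists[i] <- Inf
        j <- which.min(dists)
        p1 <- nuclei[[i]]$center; p2 <- nuclei[[j]]$center
        t_ <- seq(0, 1, length.out = ceiling(dists[j] * 2))
        bow <- sin(pi * t_) * stats::runif(1, -4, 4)
        perp <- c(-(p2 - p1)[2], (p2 - p1)[1]) / max(dists[j], 1e-9)
        pts_r <- round(p1[1] + t_ * (p2[1] - p1[1]) + bow * perp[1])
        pts_c <- round(p1[2] + t_ * (p2[2] - p1[2]) + bow * perp[2])
        keep <- pts_r >= 1 & pts_r <= n & pts_c >= 1 & pts_c <= n
        idx <- unique((pts_c[keep] - 1L) * n + pts_r[keep])
        # a bridge that would thread through an MN (or its guard ring) is
        # skipped outright; partial drawing would leave disconnected specks
        if (any(mn_guard[idx]) || any(mn_mask[idx] > 0)) next
        owner_ok <- nuc_mask[idx] %in% c(0L, i, j)
        if (!all(owner_ok)) next
        # bridge pixels belong to the nearer of the two nuclei
        rr <- ((idx - 1) %% n) + 1; cc <- ((idx - 1) %/% n) + 1
        d1 <- (rr - p1[1])^2 + (cc - p1[2])^2
        d2 <- (rr - p2[1])^2 + (cc - p2[2])^2
        owner <- ifelse(d1 <= d2, i, j)
        new <- nuc_mask[idx] == 0
        nuc_mask[idx[new]] <- owner[new]
        chrom[idx[new]] <- nuclei[[i]]$amp_c * 0.8
        rep_ch[idx[new]] <- pmax(rep_ch[idx[new]], 0.05)
        occupied[idx[new]] <- TRUE
      }
    }
  }
  n_debris <- stats::rpois(1, synth$debris_count)
  for (d in seq_len(n_debris)) {
    ctr <- stats::runif(2, 2, n - 1)
    idx <- .raster_blob(dimn, ctr, stats::runif(1, 0.8, 1.8),
                        stats::runif(1, 0.8, 1.8), 0)
    idx <- idx[!occupied[idx]]
    chrom[idx] <- stats::runif(1, 0.08, 0.2)
  }

  if (synth$blur_sigma > 0) {
    chrom <- matrix(EBImage::gblur(EBImage::Image(chrom), synth$blur_sigma), n, n)
    rep_ch <- matrix(EBImage::gblur(EBImage::Image(rep_ch), synth$blur_sigma), n, n)
  }
  chrom <- pmax(chrom + synth$background +
                  stats::rnorm(n * n, 0, synth$noise_sd), 0)
  rep_ch <- pmax(rep_ch + synth$background +
                   stats::rnorm(n * n, 0, synth$noise_sd), 0)
  dim(chrom) <- dimn; dim(rep_ch) <- dimn

  img <- field_image(list(chromatin = chrom, reporter = rep_ch),
                     resolution = synth$resolution)
  gt <- ground_truth(nuc_mask, mn_mask, mn_parent, mn_ruptured)
  list(image = img, gt = gt)
}

#' Generate a series of fields with derived seeds
#'
#' Field `i` uses seed `synth$seed + i - 1`; everything else follows the same
#' config.
#'
#' @param synth A [synth_config()].
#' @param n_fields Number of fields.
#' @return List of `generate_field()` results.
#' @export
generate_fields <- function(synth, n_fields) {
  lapply(seq_len(n_fields), function(i) {
    s <- synth
    s$seed <- synth$seed + i - 1L
    generate_field(s)
  })
}

#' Field-level split into training, validation and test sets
#'
#' Uses floor rounding for the training and validation counts and assigns the
#' remainder to the test set, so no field ever contributes to two splits.
#'
#' @param n_fields Total number of fields.
#' @param fractions Three fractions summing to 1.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_fields <- function(n_fields, fractions = c(0.65, 0.07, 0.28)) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1", call. = FALSE)
  n_train <- floor(n_fields * fractions[1])
  n_val <- floor(n_fields * fractions[2])
  n_test <- n_fields - n_train - n_val
  if (min(n_train, n_val, n_test) < 1) {
    stop("n_fields too small: every split must be non-empty", call. = FALSE)
  }
  idx <- seq_len(n_fields)
  list(train = idx[seq_len(n_train)],
       val = idx[n_train + seq_len(n_val)],
       test = idx[(n_train + n_val + 1):n_fields])
}

# pixel class labels from ground truth: 0 background, 1 nucleus, 2 MN
gt_class_matrix <- function(gt) {
  cls <- matrix(0L, nrow(gt$nucleus_mask), ncol(gt$nucleus_mask))
  cls[gt$nucleus_mask > 0] <- 1L
  cls[gt$mn_mask > 0] <- 2L
  cls
}

#' Generate a tiled, split and optionally augmented training dataset
#'
#' Generates `n_fields` synthetic fields, splits them at the field level with
#' [split_fields()], cuts each field into two-channel (raw + Sobel) tiles, and
#' attaches per-pixel class labels (background / nucleus / MN). Training tiles
#' can be augmented by 90-degree rotation and flipping; validation and test
#' tiles never are. With `targets = "maps"` each sample additionally carries
#' the foreground/distance/proximity map tiles used to train the cell-instance
#' network.
#'
#' @param synth A [synth_config()].
#' @param n_fields Number of fields to generate.
#' @param config An [mn_config()]; supplies tile size/stride and the split
#'   fractions.
#' @param augment Augment the training split. Default `TRUE`.
#' @param targets `"classes"` or `"maps"`.
#' @return List with `train`, `val`, `test` (lists of samples; each sample has
#'   `x` (H x W x 2 array), `y` (class matrix) and optionally `maps`), plus the
#'   field `split`.
#' @export
generate_training_set <- function(synth, n_fields, config = mn_config(),
                                  augment = TRUE, targets = c("classes", "maps")) {
  targets <- match.arg(targets)
  split <- split_fields(n_fields, config$split_fractions)
  fields <- generate_fields(synth, n_fields)
  set.seed(synth$seed + 7919L)  # augmentation stream, distinct from rendering

  tile_one <- function(fi) {
    f <- fields[[fi]]
    chrom <- get_channel(f$image, "chromatin")
    two_ch <- add_sobel_channel(chrom)
    cls <- gt_class_matrix(f$gt)
    maps <- if (targets == "maps") {
      make_map_set(make_cell_hulls(f$gt), dim(chrom))
    } else NULL
    tiles <- tile_field_origins(dim(chrom), config$tile_size, config$tile_stride)
    lapply(seq_len(nrow(tiles)), function(t_) {
      r <- tiles[t_, 1]; c_ <- tiles[t_, 2]; ts <- config$tile_size
      rows <- r:(r + ts - 1); cols <- c_:(c_ + ts - 1)
      s <- list(x = two_ch[rows, cols, , drop = FALSE], y = cls[rows, cols],
                field = fi, origin = c(r, c_))
      if (!is.null(maps)) {
        s$maps <- list(foreground = maps$foreground[rows, cols],
                       distance = maps$distance[rows, cols],
                       proximity = maps$proximity[rows, cols])
      }
      s
    })
  }

  aug_one <- function(s) {
    k <- sample(0:3, 1)
    fl <- stats::runif(1) < 0.5
    rot_m <- function(m) { for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE]); m }
    tf <- function(m) { m <- rot_m(m); if (fl) m <- m[nrow(m):1, , drop = FALSE]; m }
    x <- s$x
    s$x <- array(c(tf(x[, , 1]), tf(x[, , 2])), dim = dim(x))
    s$y <- tf(s$y)
    if (!is.null(s$maps)) s$maps <- lapply(s$maps, tf)
    s$augmented <- TRUE
    s
  }

  out <- list(train = list(), val = list(), test = list(), split = split)
  for (part in c("train", "val", "test")) {
    samples <- do.call(c, lapply(split[[part]], tile_one))
    if (part == "train" && augment) {
      samples <- c(samples, lapply(samples, aug_one))
    }
    out[[part]] <- samples
  }
  out
}

#' Simulate labeled reporter-intensity ratios around a rupture boundary
#'
#' Draws MN/nucleus maximum-intensity ratios for intact and ruptured MN on
#' either side of a generative decision boundary, for threshold-recovery
#' experiments.
#'
#' @param n Number of MN.
#' @param boundary Generative boundary. Default 0.16.
#' @param ruptured_fraction Fraction drawn from the ruptured side. Default 0.5.
#' @param lower,upper Support of the ruptured and intact sides.
#' @param seed Integer seed.
#' @return data.frame with columns `ratio` and `ruptured`.
#' @export
simulate_rupture_ratios <- function(n, boundary = 0.16, ruptured_fraction = 0.5,
                                    lower = 0.01, upper = 0.7, seed = 1L) {
  set.seed(seed)
  ruptured <- stats::runif(n) < ruptured_fraction
  ratio <- ifelse(ruptured,
                  stats::runif(n, lower, boundary),
                  stats::runif(n, boundary, upper))
  data.frame(ratio = ratio, ruptured = ruptured)
}
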