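# Network architectures for the two classifier families: attention-gated
# U-Nets (pixel classification of background / nucleus / MN, singly and as a
# consensus ensemble) and the multi-decoder cell-instance net predicting
# foreground, distance and proximity maps.

.unet_widths <- function(base, depth) base * 2^(seq_len(depth) - 1)

#' Build an attention-gated U-Net pixel classifier
#'
#' Encoder-decoder with skip connections, an attention gate on every decoder
#' skip, and a softmax head over the three pixel classes (background, nucleus,
#' MN). The multiscale variant additionally pools the network input to each
#' encoder scale and injects it through a 1x1 convolution, which costs strictly
#' more parameters but lets deeper blocks see raw context. Upsampling is
#' nearest-neighbour; weights are He-initialized from the given seed.
#'
#' @param in_ch Input channels (2: raw + Sobel). Crops fed to the model must
#'   have spatial sides divisible by `2^(depth-1)`.
#' @param base_width Channels of the first encoder level.
#' @param depth Number of resolution levels (including the bottleneck).
#' @param multiscale Add multiscale downsample blocks to the encoder.
#' @param n_classes Output classes. Default 3.
#' @param seed Weight-initialization seed.
#' @return An object of class `mn_pixel_model`.
#' @export
build_attention_unet <- function(in_ch = 2L, base_width = 32L, depth = 4L,
                                 multiscale = FALSE, n_classes = 3L, seed = 1L) {
  set.seed(seed)
  w <- .unet_widths(base_width, depth)
  ms_w <- max(2L, base_width %/% 2L)
  ag <- pmax(2L, w %/% 2L)
  params <- list()
  put <- function(nm, p) {
    params[[paste0(nm, "_w")]] <<- p$w
    params[[paste0(nm, "_b")]] <<- p$b
  }
  for (l in seq_len(depth)) {
    cin <- if (l == 1) in_ch else w[l - 1] + if (multiscale) ms_w else 0L
    put(paste0("enc", l, "_c1"), .init_conv(3L, cin, w[l]))
    put(paste0("enc", l, "_c2"), .init_conv(3L, w[l], w[l]))
    if (multiscale && l >= 2) put(paste0("ms", l), .init_conv(1L, in_ch, ms_w))
  }
  for (l in seq_len(depth - 1)) {
    put(paste0("upc", l), .init_conv(1L, w[l + 1], w[l]))
    put(paste0("att", l, "_theta"), .init_conv(1L, w[l], ag[l]))
    put(paste0("att", l, "_phi"), .init_conv(1L, w[l], ag[l]))
    put(paste0("att", l, "_psi"), .init_conv(1L, ag[l], 1L))
    put(paste0("dec", l, "_c1"), .init_conv(3L, 2L * w[l], w[l]))
    put(paste0("dec", l, "_c2"), .init_conv(3L, w[l], w[l]))
  }
  put("head", .init_conv(1L, w[1], n_classes))
  structure(list(arch = list(type = "attention_unet", in_ch = in_ch,
                             base_width = base_width, depth = depth,
                             multiscale = multiscale, n_classes = n_classes),
                 params = params),
            class = "mn_pixel_model")
}

# forward pass; pn is the named list of parameter nodes, x the input node
.forward_attention_unet <- function(arch, tape, pn, x) {
  conv <- function(nm, z) op_conv(tape, z, pn[[paste0(nm, "_w")]], pn[[paste0(nm, "_b")]])
  depth <- arch$depth
  enc <- vector("list", depth)
  cur <- x
  for (l in seq_len(depth)) {
    inp <- cur
    if (arch$multiscale && l >= 2) {
      ms <- conv(paste0("ms", l), op_avgpool(tape, x, 2L^(l - 1)))
      inp <- op_concat(tape, list(cur, ms))
    }
    h <- op_relu(tape, conv(paste0("enc", l, "_c1"), inp))
    h <- op_relu(tape, conv(paste0("enc", l, "_c2"), h))
    enc[[l]] <- h
    if (l < depth) cur <- op_maxpool2(tape, h)
  }
  d <- enc[[depth]]
  for (l in rev(seq_len(depth - 1))) {
    g <- conv(paste0("upc", l), op_upsample(tape, d, 2L))
    att <- op_relu(tape, op_add(tape,
                                conv(paste0("att", l, "_theta"), enc[[l]]),
                                conv(paste0("att", l, "_phi"), g)))
    gate <- op_sigmoid(tape, conv(paste0("att", l, "_psi"), att))
    xg <- op_mul_gate(tape, enc[[l]], gate)
    h <- op_relu(tape, conv(paste0("dec", l, "_c1"), op_concat(tape, list(g, xg))))
    d <- op_relu(tape, conv(paste0("dec", l, "_c2"), h))
  }
  conv("head", d)
}

# parameter nodes for a model on a fresh tape
.param_nodes <- function(tape, model) {
  lapply(model$params, function(p) op_input(tape, p))
}

#' Class-probability maps for a single tile
#'
#' Runs the network forward on one two-channel tile and returns per-pixel
#' softmax probabilities.
#'
#' @param model An `mn_pixel_model`.
#' @param tile `H x W x in_ch` numeric array.
#' @return `H x W x n_classes` array of probabilities summing to 1 per pixel.
#' @export
predict_tile_probs <- function(model, tile) {
  stopifnot(inherits(model, "mn_pixel_model"))
  tape <- nn_tape()
  pn <- .param_nodes(tape, model)
  x <- op_input(tape, array(tile, c(dim(tile)[1:2], dim(tile)[3], 1L)))
  logits <- .forward_attention_unet(model$arch, tape, pn, x)
  pr <- softmax_channels(logits$value)
  array(pr, dim(pr)[1:3])
}

# inverse-class-frequency focal alpha from a list of label matrices
.balanced_alpha <- function(ys, n_classes = 3L) {
  counts <- numeric(n_classes)
  for (y in ys) counts <- counts + tabulate(as.integer(y) + 1L, n_classes)
  counts[counts == 0] <- 1
  a <- 1 / counts
  a / sum(a) * n_classes
}

# stack a list of samples into batch arrays
.stack_batch <- function(samples) {
  d <- dim(samples[[1]]$x)
  x <- array(0, c(d[1], d[2], d[3], length(samples)))
  y <- array(0L, c(d[1], d[2], length(samples)))
  for (i in seq_along(samples)) {
    x[, , , i] <- samples[[i]]$x
    y[, , i] <- samples[[i]]$y
  }
  list(x = x, y = y)
}

#' Train a pixel-classifier U-Net with focal loss
#'
#' Minimizes the focal loss (focusing parameter `gamma`, class weights `alpha`)
#' with Adam over minibatches. All randomness (shuffling) derives from `seed`;
#' on a single thread the run is deterministic.
#'
#' @param model An `mn_pixel_model`.
#' @param samples List of samples, each `list(x = H x W x in_ch array,
#'   y = integer class matrix with values 0 (background), 1 (nucleus), 2 (MN))`.
#' @param epochs,lr,batch_size Optimization settings.
#' @param gamma Focal focusing exponent; `gamma = 0` is plain cross-entropy.
#' @param alpha `"balanced"` (inverse class frequency) or numeric class weights.
#' @param seed RNG seed for shuffling.
#' @return List with `model` (trained) and `history` (data.frame of epoch and
#'   mean training loss).
#' @export
train_pixel_model <- function(model, samples, epochs = 20L, lr = 1e-3,
                              batch_size = 8L, gamma = 2, alpha = "balanced",
                              seed = 1L) {
  stopifnot(inherits(model, "mn_pixel_model"), length(samples) > 0)
  classes_present <- sort(unique(unlist(lapply(samples, function(s) unique(as.integer(s$y))))))
  if (!all((seq_len(model$arch$n_classes) - 1L) %in% classes_present)) {
    stop("training labels must contain every class at least once", call. = FALSE)
  }
  if (identical(alpha, "balanced")) {
    alpha <- .balanced_alpha(lapply(samples, `[[`, "y"), model$arch$n_classes)
  }
  set.seed(seed)
  params <- model$params
  state <- adam_state(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample(length(samples))
    losses <- c()
    for (start in seq(1, length(ord), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1, length(ord))]
      batch <- .stack_batch(samples[bi])
      tape <- nn_tape()
      pn <- lapply(params, function(p) op_input(tape, p))
      x <- op_input(tape, batch$x)
      logits <- .forward_attention_unet(model$arch, tape, pn, x)
      loss <- op_focal_loss(tape, logits, batch$y, gamma, alpha)
      nn_backward(tape, loss)
      grads <- lapply(pn, function(nd) nd$grad)
      upd <- adam_step(params, grads, state, lr = lr)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, loss$value)
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses)))
  }
  model$params <- params
  list(model = model, history = history)
}

# --- ensemble ---------------------------------------------------------------

#' Bundle two pixel U-Nets with a consensus net
#'
#' The ensemble runs both input networks on a tile, stacks their MN-class
#' probability maps, and feeds the two-channel stack to a third (consensus)
#' U-Net. During consensus training the input networks stay frozen. The final
#' background/nucleus probabilities come from model A, the MN probability from
#' the consensus net (renormalized per pixel).
#'
#' @param model_a Plain attention U-Net (`mn_pixel_model`).
#' @param model_b Multiscale attention U-Net.
#' @param consensus Consensus U-Net with `in_ch = 2`.
#' @return An object of class `mn_ensemble`.
#' @export
ensemble_bundle <- function(model_a, model_b, consensus) {
  stopifnot(inherits(model_a, "mn_pixel_model") || inherits(model_a, "mn_oracle_pixel"),
            inherits(consensus, "mn_pixel_model"),
            consensus$arch$in_ch == 2L)
  structure(list(model_a = model_a, model_b = model_b, consensus = consensus),
            class = "mn_ensemble")
}

# MN-probability map of a model on a tile (oracle members look up their field)
.member_mn_map <- function(member, tile, origin = NULL) {
  pr <- if (inherits(member, "mn_oracle_pixel")) {
    .oracle_tile_probs(member, tile, origin)
  } else {
    predict_tile_probs(member, tile)
  }
  pr[, , 3]
}

#' Ensemble prediction on one tile
#'
#' @param bundle An [ensemble_bundle()].
#' @param tile `H x W x 2` array (raw + Sobel).
#' @param origin Tile origin (needed only when a member is an oracle backend).
#' @return `H x W x 3` probability array.
#' @export
ensemble_predict <- function(bundle, tile, origin = NULL) {
  stopifnot(inherits(bundle, "mn_ensemble"))
  pa <- if (inherits(bundle$model_a, "mn_oracle_pixel")) {
    .oracle_tile_probs(bundle$model_a, tile, origin)
  } else {
    predict_tile_probs(bundle$model_a, tile)
  }
  mn_a <- .member_mn_map(bundle$model_a, tile, origin)
  mn_b <- .member_mn_map(bundle$model_b, tile, origin)
  cons_in <- array(c(mn_a, mn_b), c(dim(mn_a), 2L))
  pc <- predict_tile_probs(bundle$consensus, cons_in)
  out <- array(0, dim(pa))
  out[, , 1] <- pa[, , 1]
  out[, , 2] <- pa[, , 2]
  out[, , 3] <- pc[, , 3]
  norm <- out[, , 1] + out[, , 2] + out[, , 3]
  for (k in 1:3) out[, , k] <- out[, , k] / norm
  out
}

#' Train the consensus net of an ensemble
#'
#' Computes the (frozen) members' MN maps for every sample, then trains only
#' the consensus network on the stacked maps. Member weights are never touched.
#'
#' @param bundle An [ensemble_bundle()].
#' @param samples As in [train_pixel_model()]; sample `origin`/`field` carried
#'   through for oracle members.
#' @param ... Passed to [train_pixel_model()].
#' @return List with the updated `bundle` and the training `history`.
#' @export
train_ensemble_consensus <- function(bundle, samples, ...) {
  cons_samples <- lapply(samples, function(s) {
    mn_a <- .member_mn_map(bundle$model_a, s$x, s$origin)
    mn_b <- .member_mn_map(bundle$model_b, s$x, s$origin)
    list(x = array(c(mn_a, mn_b), c(dim(mn_a), 2L)), y = s$y)
  })
  fit <- train_pixel_model(bundle$consensus, cons_samples, ...)
  bundle$consensus <- fit$model
  list(bundle = bundle, history = fit$history)
}

# --- oracle backend ---------------------------------------------------------

#' Oracle pixel-classifier backend from ground truth
#'
#' A test double that emits class maps equal to the ground truth (probability
#' 1 on the true class), optionally blurred with a Gaussian of width `sigma`
#' and renormalized to emulate soft network predictions. It plugs into every
#' API slot that accepts a pixel model.
#'
#' @param gt A [ground_truth()].
#' @param sigma Gaussian blur in pixels (0 = hard labels).
#' @return An object of class `mn_oracle_pixel`.
#' @export
oracle_pixel_model <- function(gt, sigma = 0) {
  cls <- gt_class_matrix(gt)
  d <- dim(cls)
  probs <- array(0, c(d, 3L))
  for (k in 0:2) probs[, , k + 1] <- (cls == k) * 1
  if (sigma > 0) {
    for (k in 1:3) {
      probs[, , k] <- as.matrix(EBImage::gblur(EBImage::Image(probs[, , k]), sigma))
    }
    norm <- probs[, , 1] + probs[, , 2] + probs[, , 3]
    norm[norm <= 0] <- 1
    for (k in 1:3) probs[, , k] <- pmax(probs[, , k], 0) / norm
  }
  structure(list(probs = probs, dim = d, sigma = sigma),
            class = "mn_oracle_pixel")
}

# tile view into the oracle's full-field probability maps
.oracle_tile_probs <- function(model, tile, origin) {
  if (is.null(origin)) stop("oracle backend needs the tile origin", call. = FALSE)
  ts <- dim(tile)[1]
  rows <- origin[1]:(origin[1] + ts - 1L)
  cols <- origin[2]:(origin[2] + dim(tile)[2] - 1L)
  model$probs[rows, cols, , drop = FALSE]
}

#' Whole-field class probabilities through the tiling + blending path
#'
#' Tiles the chromatin channel, predicts every tile with the given backend
#' (single U-Net, ensemble, or oracle), and reassembles the field by linear
#' blending. This is the inference path of the tiled segmenter.
#'
#' @param model `mn_pixel_model`, `mn_ensemble` or `mn_oracle_pixel`.
#' @param chrom Chromatin channel matrix (working resolution).
#' @param config An [mn_config()].
#' @return `H x W x 3` array of class probabilities.
#' @export
predict_field_probs <- function(model, chrom, config = mn_config()) {
  tiles <- tile_field(chrom, config)
  fd <- attr(tiles, "field_dim")
  pad <- attr(tiles, "pad")
  preds <- lapply(tiles, function(t_) {
    pr <- if (inherits(model, "mn_ensemble")) {
      ensemble_predict(model, t_$data, t_$origin - pad)
    } else if (inherits(model, "mn_oracle_pixel")) {
      .oracle_tile_probs(model, t_$data, t_$origin - pad)
    } else {
      predict_tile_probs(model, t_$data)
    }
    list(origin = t_$origin, pred = pr)
  })
  out <- blend_tiles(preds, fd, config)
  d <- dim(chrom)
  out[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), , drop = FALSE]
}

# --- cell-instance network --------------------------------------------------

#' Build the three-decoder cell-instance network
#'
#' A shared encoder feeds three decoder pathways: a foreground decoder with
#' plain skip connections (addition-merged), and distance / proximity decoders
#' with full-scale skip connections in the UNet3+ style -- every encoder level
#' and every coarser decoder level is resampled to the current scale, projected
#' by a 1x1 convolution and added -- which additionally receive the foreground
#' decoder's feature maps. The distance and proximity pathways carry a deep-
#' supervision head at every decoder scale.
#'
#' @param in_ch Input channels. Default 2.
#' @param base_width First-level width.
#' @param depth Resolution levels.
#' @param seed Initialization seed.
#' @return An object of class `mn_cell_model`.
#' @export
build_cell_net <- function(in_ch = 2L, base_width = 16L, depth = 4L, seed = 1L) {
  set.seed(seed)
  w <- .unet_widths(base_width, depth)
  cw <- base_width
  params <- list()
  put <- function(nm, p) {
    params[[paste0(nm, "_w")]] <<- p$w
    params[[paste0(nm, "_b")]] <<- p$b
  }
  for (l in seq_len(depth)) {
    cin <- if (l == 1) in_ch else w[l - 1]
    put(paste0("enc", l, "_c1"), .init_conv(3L, cin, w[l]))
    put(paste0("enc", l, "_c2"), .init_conv(3L, w[l], w[l]))
  }
  for (l in seq_len(depth - 1)) {
    put(paste0("fup", l), .init_conv(1L, w[l + 1], w[l]))
    put(paste0("fskip", l), .init_conv(1L, w[l], w[l]))
    put(paste0("fdec", l, "_c1"), .init_conv(3L, w[l], w[l]))
  }
  put("fhead", .init_conv(1L, w[1], 1L))
  for (pre in c("d", "p")) {
    for (l in seq_len(depth - 1)) {
      for (j in seq_len(depth)) {
        put(paste0(pre, "sk", l, "_", j), .init_conv(1L, w[j], cw))
      }
      cin_up <- if (l == depth - 1) w[depth] else cw
      put(paste0(pre, "up", l), .init_conv(1L, cin_up, cw))
      put(paste0(pre, "fg", l), .init_conv(1L, w[l], cw))
      put(paste0(pre, "dec", l, "_c1"), .init_conv(3L, cw, cw))
      put(paste0(pre, "head", l), .init_conv(1L, cw, 1L))
    }
  }
  structure(list(arch = list(type = "cell_net", in_ch = in_ch,
                             base_width = base_width, depth = depth,
                             n_supervision_heads = c(distance = depth - 1L,
                                                     proximity = depth - 1L)),
                 params = params),
            class = "mn_cell_model")
}

.forward_cell_net <- function(arch, tape, pn, x) {
  conv <- function(nm, z) op_conv(tape, z, pn[[paste0(nm, "_w")]], pn[[paste0(nm, "_b")]])
  depth <- arch$depth
  enc <- vector("list", depth)
  cur <- x
  for (l in seq_len(depth)) {
    h <- op_relu(tape, conv(paste0("enc", l, "_c1"), cur))
    h <- op_relu(tape, conv(paste0("enc", l, "_c2"), h))
    enc[[l]] <- h
    if (l < depth) cur <- op_maxpool2(tape, h)
  }
  # foreground decoder: plain skips, addition merge
  fdec <- vector("list", depth - 1)
  d <- enc[[depth]]
  for (l in rev(seq_len(depth - 1))) {
    up <- conv(paste0("fup", l), op_upsample(tape, d, 2L))
    sk <- conv(paste0("fskip", l), enc[[l]])
    d <- op_relu(tape, conv(paste0("fdec", l, "_c1"), op_add(tape, up, sk)))
    fdec[[l]] <- d
  }
  fg <- op_sigmoid(tape, conv("fhead", d))
  # distance / proximity decoders: full-scale skips + foreground features
  run_path <- function(pre) {
    feats <- vector("list", depth - 1)
    aux <- vector("list", depth - 1)
    prev <- enc[[depth]]
    for (l in rev(seq_len(depth - 1))) {
      acc <- conv(paste0(pre, "up", l), op_upsample(tape, prev, 2L))
      for (j in seq_len(depth)) {
        e <- enc[[j]]
        e <- if (j < l) {
          op_avgpool(tape, e, 2L^(l - j))
        } else if (j > l) {
          op_upsample(tape, e, 2L^(j - l))
        } else e
        acc <- op_add(tape, acc, conv(paste0(pre, "sk", l, "_", j), e))
      }
      acc <- op_add(tape, acc, conv(paste0(pre, "fg", l), fdec[[l]]))
      h <- op_relu(tape, conv(paste0(pre, "dec", l, "_c1"), op_relu(tape, acc)))
      feats[[l]] <- h
      head <- conv(paste0(pre, "head", l), h)
      if (l > 1) head <- op_upsample(tape, head, 2L^(l - 1))
      aux[[l]] <- op_sigmoid(tape, head)
      prev <- h
    }
    list(out = aux[[1]], aux = aux)
  }
  dist <- run_path("d")
  prox <- run_path("p")
  list(fg = fg, dist = dist$out, prox = prox$out,
       dist_aux = dist$aux, prox_aux = prox$aux)
}

#' Train the cell-instance network
#'
#' Minimizes the summed mean-squared error of the foreground map and of every
#' deep-supervision head of the distance and proximity pathways (equal
#' weights) with Adam.
#'
#' @param model An `mn_cell_model`.
#' @param samples List of samples: `x` as in [train_pixel_model()], plus
#'   `maps` (list of `foreground`, `distance`, `proximity` matrices).
#' @param epochs,lr,batch_size,seed As in [train_pixel_model()].
#' @return List with `model` and `history`.
#' @export
train_cell_net <- function(model, samples, epochs = 10L, lr = 1e-3,
                           batch_size = 8L, seed = 1L) {
  stopifnot(inherits(model, "mn_cell_model"), length(samples) > 0)
  set.seed(seed)
  params <- model$params
  state <- adam_state(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  stack_maps <- function(ss, what) {
    d <- dim(ss[[1]]$maps[[what]])
    a <- array(0, c(d[1], d[2], 1L, length(ss)))
    for (i in seq_along(ss)) a[, , 1, i] <- ss[[i]]$maps[[what]]
    a
  }
  for (ep in seq_len(epochs)) {
    ord <- sample(length(samples))
    losses <- c()
    for (start in seq(1, length(ord), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1, length(ord))]
      ss <- samples[bi]
      xb <- .stack_batch(lapply(ss, function(s) list(x = s$x, y = s$maps$foreground)))
      tfg <- stack_maps(ss, "foreground")
      tdist <- stack_maps(ss, "distance")
      tprox <- stack_maps(ss, "proximity")
      tape <- nn_tape()
      pn <- lapply(params, function(p) op_input(tape, p))
      x <- op_input(tape, xb$x)
      out <- .forward_cell_net(model$arch, tape, pn, x)
      terms <- c(list(op_mse(tape, out$fg, tfg)),
                 lapply(out$dist_aux, function(h) op_mse(tape, h, tdist)),
                 lapply(out$prox_aux, function(h) op_mse(tape, h, tprox)))
      loss <- op_sum_scalars(tape, terms)
      nn_backward(tape, loss)
      grads <- lapply(pn, function(nd) nd$grad)
      upd <- adam_step(params, grads, state, lr = lr)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, loss$value)
    }
    history <- rbind(history, data.frame(epoch = ep, loss = mean(losses)))
  }
  model$params <- params
  list(model = model, history = history)
}

#' Oracle map backend from ground truth
#'
#' Emits the exact foreground/distance/proximity maps built from the ground
#' truth hulls; plugs into [predict_map_set()] like a trained cell net.
#'
#' @param gt A [ground_truth()].
#' @param mode Hull mode, see [make_cell_hulls()].
#' @return An object of class `mn_oracle_maps`.
#' @export
oracle_map_model <- function(gt, mode = "convex") {
  hulls <- make_cell_hulls(gt, mode = mode)
  maps <- make_map_set(hulls, hulls$dim)
  structure(list(maps = maps, dim = hulls$dim), class = "mn_oracle_maps")
}

#' Predict the foreground/distance/proximity map set for a field
#'
#' Tiles the field, predicts each tile with the cell net (or looks it up in the
#' oracle's maps) and blends the tiles back; values are clipped to `[0, 1]`.
#'
#' @param model `mn_cell_model` or `mn_oracle_maps`.
#' @param chrom Chromatin channel matrix.
#' @param config An [mn_config()].
#' @return An `mn_map_set`.
#' @export
predict_map_set <- function(model, chrom, config = mn_config()) {
  tiles <- tile_field(chrom, config)
  fd <- attr(tiles, "field_dim")
  pad <- attr(tiles, "pad")
  preds <- lapply(tiles, function(t_) {
    o <- t_$origin - pad
    pr <- if (inherits(model, "mn_oracle_maps")) {
      ts <- dim(t_$data)[1:2]
      rows <- o[1]:(o[1] + ts[1] - 1L)
      cols <- o[2]:(o[2] + ts[2] - 1L)
      array(c(model$maps$foreground[rows, cols],
              model$maps$distance[rows, cols],
              model$maps$proximity[rows, cols]), c(ts, 3L))
    } else {
      tape <- nn_tape()
      pn <- .param_nodes(tape, model)
      x <- op_input(tape, array(t_$data, c(dim(t_$data)[1:2], dim(t_$data)[3], 1L)))
      out <- .forward_cell_net(model$arch, tape, pn, x)
      ts <- dim(t_$data)[1:2]
      array(c(out$fg$value, out$dist$value, out$prox$value), c(ts, 3L))
    }
    list(origin = t_$origin, pred = pr)
  })
  blended <- blend_tiles(preds, fd, config)
  d <- dim(chrom)
  blended <- blended[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), , drop = FALSE]
  structure(list(foreground = pmin(pmax(blended[, , 1], 0), 1),
                 distance = pmin(pmax(blended[, , 2], 0), 1),
                 proximity = pmin(pmax(blended[, , 3], 0), 1)),
            class = "mn_map_set")
}

#' Save / load a model with its architecture descriptor
#'
#' Stores the architecture list and all weights in a single RDS file.
#'
#' @param model A model object.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(list(class = class(model), arch = model$arch, params = model$params),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  structure(list(arch = obj$arch, params = obj$params), class = obj$class)
}
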