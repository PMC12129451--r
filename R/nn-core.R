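# Minimal reverse-mode automatic differentiation engine for the package's
# neural networks. Tensors are dense arrays of dimension (H, W, C, N); a tape
# records operations eagerly in topological order and gradients flow backwards
# through closures. Convolutions are expressed as im2col gathers followed by a
# BLAS matrix product, which keeps desk-scale training tractable in plain R.

nn_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

nn_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

.acc_grad <- function(nd, g) {
  if (is.null(g)) return(invisible(NULL))
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# backpropagate from a scalar loss node through the whole tape
nn_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd)
    for (j in seq_along(nd$parents)) {
      .acc_grad(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

op_input <- function(tape, x) nn_node(tape, x)

# 3x3 (or 1x1) same-padding convolution; w node holds array (k,k,Cin,Cout),
# b node a numeric(Cout). im2col columns are gathered by contiguous array
# slices (one per kernel offset and input channel), which keeps the heavy
# lifting in C-level subsetting and BLAS.
op_conv <- function(tape, x, w, b) {
  xd <- dim(x$value)
  wd <- dim(w$value)
  k <- wd[1]; Cin <- wd[3]; Cout <- wd[4]
  stopifnot(xd[3] == Cin)
  H <- xd[1]; W <- xd[2]; N <- xd[4]
  p <- (k - 1L) %/% 2L
  if (p > 0) {
    Hp <- H + 2L * p; Wp <- W + 2L * p
    xp <- array(0, c(Hp, Wp, Cin, N))
    xp[p + seq_len(H), p + seq_len(W), , ] <- x$value
  } else {
    xp <- x$value
  }
  K <- k * k * Cin
  PN <- H * W * N
  if (k == 1L) {
    cols <- matrix(aperm(xp, c(1, 2, 4, 3)), PN, K)
  } else {
    cols <- matrix(0, PN, K)
    r <- 0L
    for (cc in seq_len(Cin)) {
      for (dj in seq_len(k)) {
        for (di in seq_len(k)) {
          r <- r + 1L
          cols[, r] <- xp[di:(di + H - 1L), dj:(dj + W - 1L), cc, ]
        }
      }
    }
  }
  # column order (di fastest, then dj, then channel) matches matrix(w, K, Cout)
  W2 <- matrix(w$value, K, Cout)
  Y2 <- cols %*% W2
  Y2 <- Y2 + rep(b$value, each = PN)
  val <- aperm(array(Y2, c(H, W, N, Cout)), c(1, 2, 4, 3))
  nd <- nn_node(tape, val, parents = list(x, w, b), backward = function(nd) {
    dY2 <- matrix(aperm(nd$grad, c(1, 2, 4, 3)), PN, Cout)
    dW2 <- crossprod(cols, dY2)              # K x Cout
    db <- colSums(dY2)
    dcols <- tcrossprod(dY2, W2)             # PN x K
    if (k == 1L) {
      dx <- aperm(array(dcols, c(H, W, N, Cin)), c(1, 2, 4, 3))
    } else {
      dxp <- array(0, c(Hp, Wp, Cin, N))
      r <- 0L
      for (cc in seq_len(Cin)) {
        for (dj in seq_len(k)) {
          for (di in seq_len(k)) {
            r <- r + 1L
            dxp[di:(di + H - 1L), dj:(dj + W - 1L), cc, ] <-
              dxp[di:(di + H - 1L), dj:(dj + W - 1L), cc, ] + dcols[, r]
          }
        }
      }
      dx <- dxp[p + seq_len(H), p + seq_len(W), , , drop = FALSE]
    }
    list(dx, array(dW2, wd), db)
  })
  nd
}

op_relu <- function(tape, x) {
  v <- x$value
  mask <- v > 0
  nn_node(tape, v * mask, parents = list(x),
          backward = function(nd) list(nd$grad * mask))
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  nn_node(tape, s, parents = list(x),
          backward = function(nd) list(nd$grad * s * (1 - s)))
}

op_add <- function(tape, a, b) {
  nn_node(tape, a$value + b$value, parents = list(a, b),
          backward = function(nd) list(nd$grad, nd$grad))
}

op_concat <- function(tape, xs) {
  ds <- lapply(xs, function(x) dim(x$value))
  Cs <- vapply(ds, function(d) d[3], numeric(1))
  val <- array(0, c(ds[[1]][1], ds[[1]][2], sum(Cs), ds[[1]][4]))
  at <- 0L
  for (x in xs) {
    val[, , at + seq_len(dim(x$value)[3]), ] <- x$value
    at <- at + dim(x$value)[3]
  }
  nn_node(tape, val, parents = xs, backward = function(nd) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      ci <- dim(xs[[i]]$value)[3]
      out[[i]] <- nd$grad[, , at + seq_len(ci), , drop = FALSE]
      at <- at + ci
    }
    out
  })
}

op_maxpool2 <- function(tape, x) {
  d <- dim(x$value)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  ro <- seq(1L, d[1], by = 2L); co <- seq(1L, d[2], by = 2L)
  s <- list(x$value[ro, co, , , drop = FALSE],
            x$value[ro + 1L, co, , , drop = FALSE],
            x$value[ro, co + 1L, , , drop = FALSE],
            x$value[ro + 1L, co + 1L, , , drop = FALSE])
  val <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  nn_node(tape, val, parents = list(x), backward = function(nd) {
    dx <- array(0, d)
    g <- nd$grad
    taken <- array(FALSE, dim(val))  # route ties to the first maximum
    sel <- function(m) m & !taken
    m1 <- sel(s[[1]] == val); taken <- taken | m1
    m2 <- sel(s[[2]] == val); taken <- taken | m2
    m3 <- sel(s[[3]] == val); taken <- taken | m3
    m4 <- sel(s[[4]] == val)
    dx[ro, co, , ] <- g * m1
    dx[ro + 1L, co, , ] <- dx[ro + 1L, co, , , drop = FALSE] + g * m2
    dx[ro, co + 1L, , ] <- dx[ro, co + 1L, , , drop = FALSE] + g * m3
    dx[ro + 1L, co + 1L, , ] <- dx[ro + 1L, co + 1L, , , drop = FALSE] + g * m4
    list(dx)
  })
}

# nearest-neighbour upsampling by integer factor f
op_upsample <- function(tape, x, f) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = f)
  ci <- rep(seq_len(d[2]), each = f)
  val <- x$value[ri, ci, , , drop = FALSE]
  nn_node(tape, val, parents = list(x), backward = function(nd) {
    dx <- array(0, d)
    for (a in seq_len(f)) {
      for (b_ in seq_len(f)) {
        dx <- dx + nd$grad[seq(a, by = f, length.out = d[1]),
                           seq(b_, by = f, length.out = d[2]), , , drop = FALSE]
      }
    }
    list(dx)
  })
}

# average pooling by integer factor f
op_avgpool <- function(tape, x, f) {
  d <- dim(x$value)
  stopifnot(d[1] %% f == 0, d[2] %% f == 0)
  H2 <- d[1] %/% f; W2 <- d[2] %/% f
  val <- array(0, c(H2, W2, d[3], d[4]))
  for (a in seq_len(f)) {
    for (b_ in seq_len(f)) {
      val <- val + x$value[seq(a, by = f, length.out = H2),
                           seq(b_, by = f, length.out = W2), , , drop = FALSE]
    }
  }
  val <- val / (f * f)
  nn_node(tape, val, parents = list(x), backward = function(nd) {
    ri <- rep(seq_len(H2), each = f)
    ci <- rep(seq_len(W2), each = f)
    list(nd$grad[ri, ci, , , drop = FALSE] / (f * f))
  })
}

# multiply a C-channel tensor by a single-channel gate
op_mul_gate <- function(tape, x, g) {
  d <- dim(x$value)
  stopifnot(dim(g$value)[3] == 1L)
  gv <- g$value[, , rep(1L, d[3]), , drop = FALSE]
  nn_node(tape, x$value * gv, parents = list(x, g), backward = function(nd) {
    dga <- nd$grad * x$value
    dg <- array(0, dim(g$value))
    for (cc in seq_len(d[3])) dg <- dg + dga[, , cc, , drop = FALSE]
    list(nd$grad * gv, dg)
  })
}

# focal loss on raw logits (H,W,K,N) against integer class labels (H,W,N)
# in 0..K-1; alpha is a numeric(K) class weight. gamma = 0 reduces exactly to
# (weighted) cross-entropy. Returns a scalar node (mean over pixels).
op_focal_loss <- function(tape, logits, target, gamma, alpha) {
  d <- dim(logits$value)
  K <- d[3]
  np <- d[1] * d[2] * d[4]
  sl <- function(a, k) array(a[, , k, , drop = FALSE], d[c(1, 2, 4)])
  z <- logits$value
  zmax <- sl(z, 1)
  for (k in seq_len(K)[-1]) zmax <- pmax(zmax, sl(z, k))
  ez <- array(0, d)
  for (k in seq_len(K)) ez[, , k, ] <- exp(sl(z, k) - zmax)
  ssum <- sl(ez, 1)
  for (k in seq_len(K)[-1]) ssum <- ssum + sl(ez, k)
  p <- ez
  for (k in seq_len(K)) p[, , k, ] <- sl(ez, k) / ssum
  tgt <- array(target, d[c(1, 2, 4)]) + 1L  # 1-based class index
  pt <- array(0, dim(tgt))
  for (k in seq_len(K)) pt <- pt + sl(p, k) * (tgt == k)
  at <- array(alpha[tgt], dim(pt))
  eps <- 1e-12
  lvec <- -at * (1 - pt)^gamma * log(pt + eps)
  val <- sum(lvec) / np
  nn_node(tape, val, parents = list(logits), backward = function(nd) {
    # dL/dz_k = alpha_t (delta_tk - p_k) [gamma (1-pt)^(g-1) log(pt) pt - (1-pt)^g] / np
    A <- if (gamma == 0) {
      array(-1, dim(pt))
    } else {
      gamma * (1 - pt)^(gamma - 1) * log(pt + eps) * pt - (1 - pt)^gamma
    }
    dz <- array(0, d)
    for (k in seq_len(K)) {
      dz[, , k, ] <- at * ((tgt == k) - sl(p, k)) * A / np
    }
    list(dz * nd$grad)
  })
}

# mean squared error against a fixed target of the same shape
op_mse <- function(tape, pred, target) {
  diff <- pred$value - target
  n <- length(diff)
  nn_node(tape, sum(diff^2) / n, parents = list(pred),
          backward = function(nd) list(nd$grad * 2 * diff / n))
}

op_sum_scalars <- function(tape, xs, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(xs))
  val <- sum(vapply(seq_along(xs), function(i) weights[i] * xs[[i]]$value,
                    numeric(1)))
  nn_node(tape, val, parents = xs, backward = function(nd) {
    lapply(seq_along(xs), function(i) nd$grad * weights[i])
  })
}

# channel-wise softmax of a plain array (prediction-time helper, no tape)
softmax_channels <- function(z) {
  d <- dim(z)
  K <- d[3]
  sl <- function(a, k) array(a[, , k, , drop = FALSE], d[c(1, 2, 4)])
  zm <- sl(z, 1)
  for (k in seq_len(K)[-1]) zm <- pmax(zm, sl(z, k))
  ez <- array(0, d)
  for (k in seq_len(K)) ez[, , k, ] <- exp(sl(z, k) - zm)
  ssum <- sl(ez, 1)
  for (k in seq_len(K)[-1]) ssum <- ssum + sl(ez, k)
  for (k in seq_len(K)) ez[, , k, ] <- sl(ez, k) / ssum
  ez
}

# --- parameters and optimization -------------------------------------------

# He-normal weight initialization for a conv kernel
.init_conv <- function(k, cin, cout, rng_sd = NULL) {
  sd <- if (is.null(rng_sd)) sqrt(2 / (k * k * cin)) else rng_sd
  list(w = array(stats::rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout)),
       b = numeric(cout))
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# count of scalar parameters in a model
#' Number of trainable parameters of a model
#' @param model A model built by [build_attention_unet()] or [build_cell_net()].
#' @return Integer scalar.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}
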