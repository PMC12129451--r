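test_that("attention U-Net outputs valid probability maps at several sizes", {
  mod <- build_attention_unet(base_width = 4L, seed = 1)
  for (sz in c(32L, 64L)) {
    pr <- predict_tile_probs(mod, array(0, c(sz, sz, 2)))
    expect_equal(dim(pr), c(sz, sz, 3))
    expect_true(all(is.finite(pr)))
    expect_equal(pr[, , 1] + pr[, , 2] + pr[, , 3], matrix(1, sz, sz),
                 tolerance = 1e-9)
  }
})

test_that("the multiscale variant has strictly more parameters", {
  a <- build_attention_unet(base_width = 8L, multiscale = FALSE, seed = 1)
  b <- build_attention_unet(base_width = 8L, multiscale = TRUE, seed = 1)
  expect_gt(n_parameters(b), n_parameters(a))
})

test_that("training requires every class and decreases the loss on a toy task", {
  mod <- build_attention_unet(base_width = 4L, seed = 2)
  bad <- lapply(1:4, function(i) {
    list(x = array(runif(32 * 32 * 2), c(32, 32, 2)), y = matrix(0L, 32, 32))
  })
  expect_error(train_pixel_model(mod, bad, epochs = 1), "every class")
  # easy separable task: class = quantized intensity
  set.seed(4)
  samples <- lapply(1:8, function(i) {
    y <- matrix(sample(0:2, 32 * 32, TRUE), 32)
    x1 <- y / 2 + rnorm(1024, 0, 0.05)
    list(x = array(c(x1, x1 * 0), c(32, 32, 2)), y = y)
  })
  fit <- train_pixel_model(mod, samples, epochs = 5, lr = 3e-3,
                           batch_size = 8, seed = 1)
  expect_lt(utils::tail(fit$history$loss, 1), fit$history$loss[1])
})

test_that("oracle pixel backend recovers labels exactly, and nearly so when blurred", {
  f <- generate_field(synth_config(seed = 4))
  cls <- mnseg:::gt_class_matrix(f$gt)
  om <- oracle_pixel_model(f$gt, sigma = 0)
  pr <- predict_field_probs(om, get_channel(f$image, "chromatin"))
  expect_identical(apply_argmax(pr), cls)
  omb <- oracle_pixel_model(f$gt, sigma = 1)
  prb <- predict_field_probs(omb, get_channel(f$image, "chromatin"))
  clb <- apply_argmax(prb)
  obj <- cls > 0
  expect_gte(mean(clb[obj] == cls[obj]), 0.99)
})

test_that("oracle prediction is translation-consistent through tiling", {
  f <- generate_field(synth_config(seed = 6))
  om <- oracle_pixel_model(f$gt)
  chrom <- get_channel(f$image, "chromatin")
  cfg_a <- mn_config(tile_size = 128L, tile_stride = 96L)
  cfg_b <- mn_config(tile_size = 64L, tile_stride = 48L)
  pa <- predict_field_probs(om, chrom, cfg_a)
  pb <- predict_field_probs(om, chrom, cfg_b)
  expect_lt(max(abs(pa - pb)), 1e-9)
})

test_that("ensemble consensus consumes the members' MN maps and stays in simplex", {
  f <- generate_field(synth_config(seed = 8, field_size = 128L, n_cells = 2L))
  om <- oracle_pixel_model(f$gt)
  cons <- build_attention_unet(in_ch = 2L, base_width = 4L, seed = 3)
  bundle <- ensemble_bundle(om, om, cons)
  tile <- add_sobel_channel(get_channel(f$image, "chromatin"))
  pr <- ensemble_predict(bundle, tile, origin = c(1L, 1L))
  expect_equal(dim(pr), c(128, 128, 3))
  expect_equal(pr[, , 1] + pr[, , 2] + pr[, , 3], matrix(1, 128, 128),
               tolerance = 1e-9)
})

test_that("consensus training with frozen oracle members reaches high MN recall", {
  cfg <- mn_config(tile_size = 32L, tile_stride = 32L)
  samples <- list()
  for (f in generate_fields(synth_config(seed = 21), 6)) {
    om <- oracle_pixel_model(f$gt, sigma = 1)
    cls <- mnseg:::gt_class_matrix(f$gt)
    for (t_ in tile_field(get_channel(f$image, "chromatin"), cfg)) {
      o <- t_$origin
      rows <- o[1]:(o[1] + 31); cols <- o[2]:(o[2] + 31)
      if (mean(cls[rows, cols] > 0) < 0.02) next
      mn <- om$probs[rows, cols, 3]
      samples[[length(samples) + 1]] <- list(x = array(c(mn, mn), c(32, 32, 2)),
                                             y = cls[rows, cols])
    }
  }
  expect_gte(length(samples), 120)
  cons <- build_attention_unet(in_ch = 2L, base_width = 8L, seed = 5)
  w_before <- samples[[1]]$x  # members are data here; nothing can change them
  fit <- train_pixel_model(cons, samples[1:100], epochs = 8, lr = 2e-3,
                           batch_size = 16, seed = 2)
  tp <- 0; fn <- 0
  for (s in samples[101:length(samples)]) {
    cl <- apply_argmax(predict_tile_probs(fit$model, s$x))
    tp <- tp + sum(cl == 2 & s$y == 2)
    fn <- fn + sum(cl != 2 & s$y == 2)
  }
  expect_gt(tp / (tp + fn), 0.9)
  expect_identical(samples[[1]]$x, w_before)
})

test_that("cell net emits three bounded maps with one supervision head per scale", {
  cn <- build_cell_net(base_width = 4L, seed = 1)
  expect_equal(unname(cn$arch$n_supervision_heads["distance"]), cn$arch$depth - 1L)
  expect_equal(unname(cn$arch$n_supervision_heads["proximity"]), cn$arch$depth - 1L)
  expect_length(grep("^dhead", names(cn$params)), 2L * (cn$arch$depth - 1L))
  tape <- mnseg:::nn_tape()
  pn <- lapply(cn$params, function(p) mnseg:::op_input(tape, p))
  x <- mnseg:::op_input(tape, array(0, c(32, 32, 2, 1)))
  out <- mnseg:::.forward_cell_net(cn$arch, tape, pn, x)
  for (nm in c("fg", "dist", "prox")) {
    v <- out[[nm]]$value
    expect_equal(dim(v)[1:2], c(32, 32))
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_length(out$dist_aux, cn$arch$depth - 1L)
  for (h in out$dist_aux) expect_equal(dim(h$value)[1:2], c(32, 32))
})

test_that("a briefly trained cell net beats a constant-0.5 distance predictor", {
  cfg <- mn_config(tile_size = 32L, tile_stride = 32L)
  ts <- generate_training_set(synth_config(seed = 31), n_fields = 15,
                              config = cfg, augment = FALSE, targets = "maps")
  pool <- ts$train[vapply(ts$train, function(s) mean(s$maps$foreground) >= 0.05,
                          logical(1))]
  set.seed(7)
  train <- pool[sample(length(pool), min(80, length(pool)))]
  cn <- build_cell_net(base_width = 8L, seed = 4)
  fit <- train_cell_net(cn, train, epochs = 6, lr = 2e-3, batch_size = 16,
                        seed = 3)
  expect_lt(utils::tail(fit$history$loss, 1), fit$history$loss[1])
  mae_net <- c(); mae_const <- c()
  for (s in ts$test[seq(1, length(ts$test), by = 4)]) {
    tape <- mnseg:::nn_tape()
    pn <- lapply(fit$model$params, function(p) mnseg:::op_input(tape, p))
    x <- mnseg:::op_input(tape, array(s$x, c(32, 32, 2, 1)))
    out <- mnseg:::.forward_cell_net(fit$model$arch, tape, pn, x)
    mae_net <- c(mae_net, mean(abs(out$dist$value[, , 1, 1] - s$maps$distance)))
    mae_const <- c(mae_const, mean(abs(0.5 - s$maps$distance)))
  }
  expect_lt(mean(mae_net), mean(mae_const))
})

test_that("oracle map backend round-trips through tiling within 1e-6", {
  f <- generate_field(synth_config(seed = 9))
  om <- oracle_map_model(f$gt)
  pred <- predict_map_set(om, get_channel(f$image, "chromatin"), mn_config())
  expect_lt(max(abs(pred$distance - om$maps$distance)), 1e-6)
  expect_lt(max(abs(pred$proximity - om$maps$proximity)), 1e-6)
  expect_lt(max(abs(pred$foreground - om$maps$foreground)), 1e-6)
})

test_that("models survive a save/load round trip", {
  mod <- build_attention_unet(base_width = 4L, seed = 11)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(mod, path)
  back <- load_model(path)
  expect_identical(back$params, mod$params)
  expect_identical(back$arch, mod$arch)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  expect_identical(predict_tile_probs(mod, x), predict_tile_probs(back, x))
})
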