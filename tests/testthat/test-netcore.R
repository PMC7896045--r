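# Receptive-field and shape calculus, pooling heads, loss, training loop.

test_that("receptive-field recurrence reproduces hand-derived and reference values", {
  one_conv <- architecture_spec(list(layer_spec("conv", 3, 1, channels = 1)), 1)
  expect_equal(receptive_field(one_conv), list(rf_px = 3L, jump_px = 1L))

  stem <- architecture_spec(list(layer_spec("conv", 7, 2, channels = 64),
                                 layer_spec("pool", 3, 2)), 64)
  expect_equal(receptive_field(stem), list(rf_px = 11L, jump_px = 4L))

  rf <- receptive_field(resnet50_spec())
  expect_identical(rf$rf_px, 483L)
  expect_identical(rf$jump_px, 32L)
})

test_that("shape recurrence matches the same-padding rule", {
  r50 <- resnet50_spec()
  expect_identical(output_spatial_size(r50, 224), 7L)
  expect_identical(output_spatial_size(r50, 21500), 672L)
  ident <- architecture_spec(list(layer_spec("identity")), 1)
  expect_identical(output_spatial_size(ident, 57), 57L)
})

test_that("physical receptive field converts pixels to microns", {
  expect_equal(physical_receptive_field(483, 2.3), 1111)
  expect_equal(physical_receptive_field(483, 4.6), 2222)
  expect_equal(physical_receptive_field(483, 0.46), 222)
})

test_that("receptive field agrees with brute-force influence probing", {
  # linear conv stacks with positive weights: an input pixel influences the
  # centre output cell iff it lies in that cell's receptive field
  archs <- list(
    list(c(3, 1)),
    list(c(3, 2), c(3, 1)),
    list(c(5, 2)),
    list(c(3, 1), c(3, 1), c(3, 1)),
    list(c(7, 2), c(3, 2)))
  for (layers in archs) {
    spec <- architecture_spec(
      lapply(layers, function(ks) layer_spec("conv", ks[1], ks[2], channels = 1)),
      1)
    rf <- receptive_field(spec)$rf_px
    n <- 2 * rf + 9
    ws <- lapply(layers, function(ks)
      matrix(1, nrow = ks[1]^2, ncol = 1))
    fwd <- function(x) {
      for (i in seq_along(layers))
        x <- wsiweak:::conv2d_fw(x, ws[[i]], 0, layers[[i]][1], layers[[i]][2])
      x
    }
    base <- fwd(array(0, dim = c(n, n, 1)))
    ctr <- (dim(base)[1] + 1) %/% 2
    influenced <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      x <- array(0, dim = c(n, n, 1)); x[i, j, 1] <- 1
      influenced[i, j] <- fwd(x)[ctr, ctr, 1] != base[ctr, ctr, 1]
    }
    side_r <- diff(range(which(apply(influenced, 1, any)))) + 1
    side_c <- diff(range(which(apply(influenced, 2, any)))) + 1
    expect_identical(as.integer(max(side_r, side_c)), as.integer(rf))
  }
})

test_that("global pooling heads follow their definitions", {
  fm <- array(c(1, 3, 5, 2), dim = c(2, 2, 1))
  expect_equal(gap(fm), 2.75)
  expect_equal(gmp(fm), 5)
  const <- array(4.2, dim = c(3, 3, 2))
  expect_equal(gmp(const), gap(const))
  one <- array(9, dim = c(1, 1, 3))
  expect_equal(gmp(one), c(9, 9, 9))
  withr::with_seed(1, {
    rnd <- array(rnorm(7 * 7 * 4), dim = c(7, 7, 4))
    expect_true(all(gmp(rnd) >= gap(rnd)))
  })
})

test_that("cross-entropy has the closed-form values and permutation symmetry", {
  expect_equal(cross_entropy(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(cross_entropy(c(1, 0, 0), rep(1 / 3, 3)), log(3))
  expect_equal(cross_entropy(c(0, 0, 1), c(0.3, 0.2, 0.5)), log(2))
  p <- c(0.2, 0.5, 0.3)
  expect_equal(cross_entropy(c(0, 1, 0), p),
               cross_entropy(c(0, 1, 0)[c(2, 1, 3)], p[c(2, 1, 3)]))
  expect_error(cross_entropy(c(0.5, 0.5, 0), p), "one-hot")
  expect_true(is.finite(cross_entropy(c(1, 0, 0), c(0, 0.5, 0.5))))
})

test_that("training is seed-deterministic, converges on separable tiles, and keeps lr without patience", {
  images <- list(); labels <- integer(0)
  for (cl in 1:3) for (r in 1:6) {
    images[[length(images) + 1]] <- toy_tile(cl, seed = cl * 100 + r)
    labels <- c(labels, cl)
  }
  val_im <- lapply(1:3, function(cl) toy_tile(cl, seed = cl * 991))
  cfg <- train_config(batch_size = 4L, lr_initial = 3e-3, lr_decayed = 3e-4,
                      patience_epochs = 24L, steps_per_epoch = 5L,
                      epochs = 12L, seed = 42L)
  batch_fn <- function(epoch, step) {
    idx <- withr::with_seed(derive_seed(cfg$seed, paste(epoch, step)),
                            sample.int(length(images), cfg$batch_size))
    list(images = images[idx], labels = labels[idx])
  }
  val_fn <- function(m) {
    loss <- 0; correct <- 0
    for (cl in 1:3) {
      p <- nn_predict(m, val_im[[cl]])
      loss <- loss + cross_entropy(as.numeric(1:3 == cl), p)
      correct <- correct + (which.max(p) == cl)
    }
    c(loss = loss / 3, acc = correct / 3)
  }
  run <- function() nn_train(nn_init(tile_arch(), "gap", seed = 3),
                             batch_fn, val_fn, cfg)
  f1 <- run(); f2 <- run()
  expect_identical(f1$curves, f2$curves)
  expect_equal(max(f1$curves$train_acc), 1.0)
  expect_true(which.max(f1$curves$train_acc == 1) <= 20)
  expect_true(all(f1$curves$lr == cfg$lr_initial))
})
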