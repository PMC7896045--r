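## Compact convolutional network engine.
##
## Executes the "conv" layers of an architecture_spec with ReLU activations,
## a GAP or GMP head and a linear 3-class output. Forward/backward convolution
## runs in C++ (im2col + GEMM, 'same' padding); everything else is plain R.
## Inputs are 0-255 RGB arrays, standardized internally to [-0.5, 0.5].

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Initialize a compact convolutional classifier
#'
#' Weights use He-style initialization (zero-mean Gaussians with variance
#' 2 / fan-in) and zero biases; the head is a linear map from the pooled
#' feature vector to class logits.
#'
#' @param arch an [architecture_spec()] whose layers are all "conv".
#' @param head "gmp" (global max pooling) or "gap" (global average pooling).
#' @param n_classes number of output classes.
#' @param seed integer seed for weight initialization.
#' @param in_channels input image channels.
#' @return an `nn_model` object.
#' @export
nn_init <- function(arch, head = c("gmp", "gap"), n_classes = 3L,
                    seed = 1L, in_channels = 3L) {
  head <- match.arg(head)
  stopifnot(inherits(arch, "architecture_spec"),
            all(vapply(arch$layers, function(l) l$kind == "conv", logical(1))))
  layers <- list()
  cin <- in_channels
  Wd <- NULL
  with_seed(derive_seed(seed, "nn-init"), {
    for (ly in arch$layers) {
      fan_in <- ly$k * ly$k * cin
      W <- matrix(rnorm(fan_in * ly$channels, sd = sqrt(2 / fan_in)),
                  nrow = fan_in, ncol = ly$channels)
      layers[[length(layers) + 1L]] <- list(W = W, b = numeric(ly$channels),
                                            k = ly$k, s = ly$s)
      cin <- ly$channels
    }
    Wd <- matrix(rnorm(cin * n_classes, sd = sqrt(1 / cin)),
                 nrow = cin, ncol = n_classes)
  })
  structure(list(layers = layers, Wd = Wd, bd = numeric(n_classes),
                 head = head, n_classes = as.integer(n_classes),
                 arch = arch),
            class = "nn_model")
}

#' Forward pass of the compact classifier
#'
#' @param model an `nn_model`.
#' @param img H x W x 3 numeric/integer array with values in 0-255.
#' @param keep_cache keep layer activations for a subsequent backward pass.
#' @return list with `probs` (class probabilities), `logits`, `pooled`
#'   (pre-head embedding), `feature_map` (final h x w x C activations) and,
#'   if requested, `cache`.
#' @export
nn_forward <- function(model, img, keep_cache = FALSE) {
  x <- array(as.numeric(img) / 255 - 0.5, dim = dim(img))
  cache <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    pre <- conv2d_fw(x, ly$W, ly$b, ly$k, ly$s)
    if (keep_cache) cache[[i]] <- list(x = x, pre = pre)
    x <- pre
    x[x < 0] <- 0
  }
  fm <- x
  hw <- dim(fm)[1] * dim(fm)[2]
  fmat <- matrix(fm, nrow = hw)
  if (model$head == "gmp") {
    idx <- max.col(t(fmat), ties.method = "first")
    pooled <- fmat[cbind(idx, seq_len(ncol(fmat)))]
  } else {
    idx <- NULL
    pooled <- colMeans(fmat)
  }
  logits <- drop(crossprod(model$Wd, pooled)) + model$bd
  out <- list(probs = softmax(logits), logits = logits, pooled = pooled,
              feature_map = fm)
  if (keep_cache) out$cache <- list(layers = cache, pool_idx = idx, hw = hw)
  out
}

# Gradients of the cross-entropy loss for one image; returns a list shaped
# like the model parameters.
nn_backward <- function(model, fwd, label_index) {
  y <- numeric(model$n_classes)
  y[label_index] <- 1
  dlogits <- fwd$probs - y
  dWd <- outer(fwd$pooled, dlogits)
  dbd <- dlogits
  dpooled <- drop(model$Wd %*% dlogits)

  fm <- fwd$feature_map
  d <- dim(fm)
  dfm_mat <- matrix(0, nrow = d[1] * d[2], ncol = d[3])
  if (model$head == "gmp") {
    dfm_mat[cbind(fwd$cache$pool_idx, seq_len(d[3]))] <- dpooled
  } else {
    dfm_mat <- matrix(rep(dpooled / (d[1] * d[2]), each = d[1] * d[2]),
                      nrow = d[1] * d[2])
  }
  dx <- array(dfm_mat, dim = d)

  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    lc <- fwd$cache$layers[[i]]
    dx[lc$pre < 0] <- 0
    bw <- conv2d_bw(lc$x, model$layers[[i]]$W, dx,
                    model$layers[[i]]$k, model$layers[[i]]$s)
    grads[[i]] <- list(dW = bw$dW, db = as.numeric(bw$db))
    dx <- bw$dx
  }
  list(layers = grads, dWd = dWd, dbd = dbd,
       loss = cross_entropy(y, fwd$probs))
}

# Average loss and gradients over a batch of (image, label) pairs.
nn_batch_grads <- function(model, images, labels) {
  n <- length(images)
  acc <- NULL
  loss <- 0
  correct <- 0
  for (i in seq_len(n)) {
    fwd <- nn_forward(model, images[[i]], keep_cache = TRUE)
    g <- nn_backward(model, fwd, labels[i])
    loss <- loss + g$loss
    correct <- correct + (which.max(fwd$probs) == labels[i])
    if (is.null(acc)) {
      acc <- g
    } else {
      for (l in seq_along(acc$layers)) {
        acc$layers[[l]]$dW <- acc$layers[[l]]$dW + g$layers[[l]]$dW
        acc$layers[[l]]$db <- acc$layers[[l]]$db + g$layers[[l]]$db
      }
      acc$dWd <- acc$dWd + g$dWd
      acc$dbd <- acc$dbd + g$dbd
    }
  }
  for (l in seq_along(acc$layers)) {
    acc$layers[[l]]$dW <- acc$layers[[l]]$dW / n
    acc$layers[[l]]$db <- acc$layers[[l]]$db / n
  }
  acc$dWd <- acc$dWd / n
  acc$dbd <- acc$dbd / n
  list(grads = acc, loss = loss / n, acc = correct / n)
}

adam_init <- function(model) {
  zero_like <- function(x) if (is.matrix(x)) x * 0 else numeric(length(x))
  st <- list(t = 0, m = list(), v = list())
  params <- nn_param_list(model)
  st$m <- lapply(params, zero_like)
  st$v <- lapply(params, zero_like)
  st
}

nn_param_list <- function(model) {
  p <- list()
  for (i in seq_along(model$layers)) {
    p[[paste0("W", i)]] <- model$layers[[i]]$W
    p[[paste0("b", i)]] <- model$layers[[i]]$b
  }
  p$Wd <- model$Wd
  p$bd <- model$bd
  p
}

nn_set_params <- function(model, p) {
  for (i in seq_along(model$layers)) {
    model$layers[[i]]$W <- p[[paste0("W", i)]]
    model$layers[[i]]$b <- p[[paste0("b", i)]]
  }
  model$Wd <- p$Wd
  model$bd <- p$bd
  model
}

nn_grad_list <- function(grads) {
  g <- list()
  for (i in seq_along(grads$layers)) {
    g[[paste0("W", i)]] <- grads$layers[[i]]$dW
    g[[paste0("b", i)]] <- grads$layers[[i]]$db
  }
  g$Wd <- grads$dWd
  g$bd <- grads$dbd
  g
}

adam_step <- function(model, state, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  p <- nn_param_list(model)
  g <- nn_grad_list(grads)
  for (nm in names(p)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(model = nn_set_params(model, p), state = state)
}

#' Training configuration
#'
#' Defaults mirror the reference training schedule: Adam with an initial
#' learning rate of 2e-5 decaying once to 2e-6 when the validation loss has
#' not improved for 24 epochs, batch size 8, an "epoch" defined as 100
#' optimizer steps, and checkpointing the weights with the lowest validation
#' loss. Desk-scale presets override the rates and sizes; the schedule logic
#' is identical. `lr_gpu_scale` records the square-root-of-GPU-count
#' multiplier used by synchronized data parallelism; execution here is
#' single-process so it defaults to 1 and is purely documentary.
#'
#' @param batch_size images per optimizer step.
#' @param lr_initial,lr_decayed Adam learning rates before/after decay.
#' @param patience_epochs epochs without validation improvement before decay.
#' @param steps_per_epoch optimizer steps per epoch.
#' @param epochs total epochs to run.
#' @param seed master seed for sampling and initialization.
#' @param lr_gpu_scale documentary multi-accelerator learning-rate multiplier.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 8L, lr_initial = 2e-5, lr_decayed = 2e-6,
                         patience_epochs = 24L, steps_per_epoch = 100L,
                         epochs = 30L, seed = 1L, lr_gpu_scale = 1) {
  stopifnot(lr_decayed < lr_initial, patience_epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), lr_initial = lr_initial,
                 lr_decayed = lr_decayed,
                 patience_epochs = as.integer(patience_epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 lr_gpu_scale = lr_gpu_scale),
            class = "train_config")
}

#' Train a compact classifier
#'
#' Runs Adam over batches drawn by `batch_fn`, evaluating `val_fn` once per
#' epoch (an epoch is `steps_per_epoch` optimizer steps). The learning rate
#' decays once from `lr_initial` to `lr_decayed` when validation loss has not
#' improved for `patience_epochs` epochs; the returned model carries the
#' weights with the lowest validation loss seen.
#'
#' @param model an `nn_model`.
#' @param batch_fn function(epoch, step) returning
#'   `list(images = list of arrays, labels = integer vector)`.
#' @param val_fn function(model) returning `c(loss = , acc = )`.
#' @param cfg a [train_config()].
#' @return list with `model` (best checkpoint) and `curves` (one row per
#'   epoch: losses, accuracies, learning rate).
#' @export
nn_train <- function(model, batch_fn, val_fn, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  state <- adam_init(model)
  lr <- cfg$lr_initial
  best <- list(loss = Inf, model = model, epoch = 0L)
  curves <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    tl <- 0; ta <- 0
    for (step in seq_len(cfg$steps_per_epoch)) {
      batch <- batch_fn(epoch, step)
      bg <- nn_batch_grads(model, batch$images, batch$labels)
      if (!is.finite(bg$loss))
        stop(sprintf("non-finite training loss at epoch %d step %d", epoch, step))
      upd <- adam_step(model, state, bg$grads, lr)
      model <- upd$model
      state <- upd$state
      tl <- tl + bg$loss; ta <- ta + bg$acc
    }
    v <- val_fn(model)
    if (v[["loss"]] < best$loss) {
      best <- list(loss = v[["loss"]], model = model, epoch = epoch)
    }
    if (epoch - best$epoch >= cfg$patience_epochs) lr <- cfg$lr_decayed
    curves <- rbind(curves, data.frame(
      epoch = epoch,
      train_loss = tl / cfg$steps_per_epoch,
      train_acc = ta / cfg$steps_per_epoch,
      val_loss = unname(v[["loss"]]), val_acc = unname(v[["acc"]]),
      lr = lr))
  }
  list(model = best$model, curves = curves)
}

#' Predict class probabilities for one image
#' @param model an `nn_model`.
#' @param img H x W x 3 array, 0-255.
#' @return numeric vector of class probabilities.
#' @export
nn_predict <- function(model, img) nn_forward(model, img)$probs

#' Pre-head embedding of one image
#' @inheritParams nn_predict
#' @return pooled feature vector (length = final channels).
#' @export
nn_embed <- function(model, img) nn_forward(model, img)$pooled
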