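## Recurrent aggregation of top-k instance embeddings (MIL-RNN).
##
## A single-layer tanh RNN with 128 hidden units consumes the top-k instance
## embeddings in descending-score order; the final hidden state feeds a
## 3-way softmax.

#' Initialize the recurrent bag aggregator
#'
#' @param input_dim embedding dimension of an instance.
#' @param hidden hidden units (128 in the reference configuration).
#' @param n_classes output classes.
#' @param seed seed for weight initialization.
#' @return an `rnn_model`.
#' @export
rnn_init <- function(input_dim, hidden = 128L, n_classes = 3L, seed = 1L) {
  with_seed(derive_seed(seed, "rnn-init"), {
    structure(list(
      Wx = matrix(rnorm(input_dim * hidden, sd = 1 / sqrt(input_dim)),
                  input_dim, hidden),
      Wh = matrix(rnorm(hidden * hidden, sd = 1 / sqrt(hidden)), hidden, hidden),
      bh = numeric(hidden),
      Wo = matrix(rnorm(hidden * n_classes, sd = 1 / sqrt(hidden)),
                  hidden, n_classes),
      bo = numeric(n_classes),
      hidden = as.integer(hidden), n_classes = as.integer(n_classes)),
      class = "rnn_model")
  })
}

#' Aggregate an ordered embedding sequence into class probabilities
#'
#' @param rnn an `rnn_model`.
#' @param x T x d matrix of embeddings, descending instance score order.
#' @return named class probability vector.
#' @export
rnn_aggregate <- function(rnn, x) {
  rnn_forward(rnn, x)$probs
}

rnn_forward <- function(rnn, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0) stop("empty embedding sequence")
  h <- numeric(rnn$hidden)
  hs <- matrix(0, nrow(x), rnn$hidden)
  as_ <- matrix(0, nrow(x), rnn$hidden)
  for (t in seq_len(nrow(x))) {
    a <- drop(crossprod(rnn$Wx, x[t, ])) + drop(crossprod(rnn$Wh, h)) + rnn$bh
    h <- tanh(a)
    as_[t, ] <- a; hs[t, ] <- h
  }
  logits <- drop(crossprod(rnn$Wo, h)) + rnn$bo
  p <- softmax(logits)
  names(p) <- CLASS_LEVELS[seq_along(p)]
  list(probs = p, hs = hs, as_ = as_, x = x)
}

rnn_backward <- function(rnn, fwd, label_index) {
  y <- numeric(rnn$n_classes); y[label_index] <- 1
  dlogits <- fwd$probs - y
  Tn <- nrow(fwd$x)
  hT <- fwd$hs[Tn, ]
  g <- list(Wx = rnn$Wx * 0, Wh = rnn$Wh * 0, bh = numeric(rnn$hidden),
            Wo = outer(hT, as.numeric(dlogits)), bo = as.numeric(dlogits))
  dh <- drop(rnn$Wo %*% dlogits)
  for (t in rev(seq_len(Tn))) {
    da <- dh * (1 - fwd$hs[t, ]^2)
    g$Wx <- g$Wx + outer(fwd$x[t, ], da)
    hprev <- if (t > 1) fwd$hs[t - 1, ] else numeric(rnn$hidden)
    g$Wh <- g$Wh + outer(hprev, da)
    g$bh <- g$bh + da
    dh <- drop(rnn$Wh %*% da)
  }
  g$loss <- cross_entropy(y, fwd$probs)
  g
}

#' Train the recurrent bag aggregator
#'
#' Adam over minibatches of embedding sequences.
#'
#' @param rnn an `rnn_model`.
#' @param seqs list of T x d embedding matrices (descending score order).
#' @param labels integer class indices (1 = NC, 2 = ADC, 3 = SqCC).
#' @param epochs,lr,batch_size optimization settings.
#' @param seed seed for shuffling.
#' @return the trained `rnn_model`.
#' @export
rnn_train <- function(rnn, seqs, labels, epochs = 30L, lr = 5e-3,
                      batch_size = 16L, seed = 1L) {
  stopifnot(length(seqs) == length(labels))
  nm <- c("Wx", "Wh", "bh", "Wo", "bo")
  st <- list(t = 0,
             m = lapply(rnn[nm], function(p) p * 0),
             v = lapply(rnn[nm], function(p) p * 0))
  for (e in seq_len(epochs)) {
    perm <- with_seed(derive_seed(seed, paste0("rnn-epoch-", e)),
                      sample.int(length(seqs)))
    for (start in seq(1, length(seqs), by = batch_size)) {
      rows <- perm[start:min(start + batch_size - 1, length(seqs))]
      acc <- NULL
      for (r in rows) {
        fwd <- rnn_forward(rnn, seqs[[r]])
        g <- rnn_backward(rnn, fwd, labels[r])
        if (is.null(acc)) acc <- g
        else for (p in nm) acc[[p]] <- acc[[p]] + g[[p]]
      }
      st$t <- st$t + 1
      for (p in nm) {
        grad <- acc[[p]] / length(rows)
        st$m[[p]] <- 0.9 * st$m[[p]] + 0.1 * grad
        st$v[[p]] <- 0.999 * st$v[[p]] + 0.001 * grad^2
        mh <- st$m[[p]] / (1 - 0.9^st$t)
        vh <- st$v[[p]] / (1 - 0.999^st$t)
        rnn[[p]] <- rnn[[p]] - lr * mh / (sqrt(vh) + 1e-8)
      }
    }
  }
  rnn
}
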