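## Multiple-instance learning baselines.
##
## A slide is a bag; its non-background 224x224 tiles are instances. The
## standard baseline alternates instance selection (top-k by the bag's own
## cancer class probability) with classifier optimization on the selected
## instances; bag-level inference takes channel-wise maxima. Variants: EM
## selection on blurred prediction maps, class-histogram bag classifiers
## (logistic regression / RBF-SVM), max-feature random forests and recurrent
## aggregation of top-k embeddings.

#' Build bags of non-background tiles
#'
#' Tiles each slide on the 224 grid (virtual white padding at the
#' bottom/right border) and keeps non-background tiles. Tile pixels are not
#' materialized; bags store grid coordinates and an index into `slides`.
#'
#' @param slides list of `labeled_slide` objects.
#' @param tile tile side in pixels.
#' @return list of bags: each has `slide_id`, `label`, `slide_index`,
#'   `coords` (n x 2 matrix of 0-based grid_row, grid_col) and `grid_dim`.
#' @export
make_bags <- function(slides, tile = TILE_PX) {
  bags <- list()
  for (si in seq_along(slides)) {
    s <- slides[[si]]
    d <- dim(s$image)
    gr <- ceiling(d[1] / tile); gc <- ceiling(d[2] / tile)
    coords <- NULL
    for (r in seq_len(gr) - 1L)
      for (cc in seq_len(gc) - 1L)
        if (!is_background(extract_tile(s$image, r, cc, tile)))
          coords <- rbind(coords, c(r, cc))
    if (is.null(coords)) {
      warning(sprintf("slide %s has only background tiles; skipped", s$slide_id))
      next
    }
    bags[[s$slide_id]] <- list(slide_id = s$slide_id, label = s$label,
                               slide_index = si, coords = coords,
                               grid_dim = c(gr, gc), tile = tile)
  }
  bags
}

# Fetch the pixels of instance i of a bag.
bag_tile <- function(slides, bag, i) {
  extract_tile(slides[[bag$slide_index]]$image,
               bag$coords[i, 1], bag$coords[i, 2], bag$tile)
}

#' Score all instances of a bag
#'
#' One forward pass per tile; scores are order-aligned with the bag's
#' instances. Also returns the pre-head embeddings, which the max-feature
#' and recurrent aggregators consume.
#'
#' @param model an `nn_model` tile classifier.
#' @param bag a bag from [make_bags()].
#' @param slides the slide list the bag indexes into.
#' @return list with `probs` (n x 3 matrix, columns NC/ADC/SqCC) and
#'   `embeddings` (n x C matrix).
#' @export
score_instances <- function(model, bag, slides) {
  n <- nrow(bag$coords)
  if (n == 0) stop("empty bag")
  probs <- matrix(0, n, model$n_classes)
  emb <- NULL
  for (i in seq_len(n)) {
    fwd <- nn_forward(model, bag_tile(slides, bag, i))
    probs[i, ] <- fwd$probs
    if (is.null(emb)) emb <- matrix(0, n, length(fwd$pooled))
    emb[i, ] <- fwd$pooled
  }
  colnames(probs) <- CLASS_LEVELS
  list(probs = probs, embeddings = emb)
}

#' Select the top-k instances for a class
#'
#' Indices of the k highest target-class probabilities; ties break toward
#' the lowest instance index (row-major grid order); k is clipped to the bag
#' size.
#'
#' @param scores n x 3 matrix (or numeric vector of target-class scores).
#' @param target_class "NC", "ADC" or "SqCC" (ignored for a vector input).
#' @param k number of instances to select.
#' @return list with `indices` (distinct, length min(k, n)) and `k`.
#' @export
select_topk <- function(scores, target_class = "ADC", k = 1L) {
  stopifnot(k >= 1)
  s <- if (is.matrix(scores)) scores[, target_class] else scores
  n <- length(s)
  if (n == 0) stop("empty score list")
  ord <- order(-s, seq_len(n))
  list(indices = ord[seq_len(min(k, n))], k = as.integer(k))
}

#' Bag-level inference by max aggregation
#'
#' Each cancer class scores the maximum of its instance probabilities; the
#' non-cancer score is 1 minus the best cancer score (floored at 0); the
#' triple is renormalized. Permutation-invariant over instances.
#'
#' @param scores n x 3 instance probability matrix.
#' @return named numeric vector of slide-level class probabilities.
#' @export
infer_bag_max <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (nrow(scores) == 0) stop("empty bag")
  s_adc <- max(scores[, 2]); s_sqcc <- max(scores[, 3])
  s_nc <- max(0, 1 - max(s_adc, s_sqcc))
  p <- c(NC = s_nc, ADC = s_adc, SqCC = s_sqcc)
  p / sum(p)
}

# 3x3 Gaussian kernel (sigma = 1) used for prediction-map blurring.
gaussian3x3 <- function(sigma = 1) {
  w <- exp(-(c(-1, 0, 1)^2) / (2 * sigma^2))
  outer(w, w)
}

# Masked 3x3 blur: conv(P * M * K) / conv(M * K); cells outside the mask
# stay NA.
masked_blur3 <- function(p, mask, sigma = 1) {
  K <- gaussian3x3(sigma)
  num <- matrix(0, nrow(p), ncol(p))
  den <- matrix(0, nrow(p), ncol(p))
  pm <- p * mask
  for (di in -1:1) for (dj in -1:1) {
    w <- K[di + 2, dj + 2]
    rs <- seq_len(nrow(p)); cs <- seq_len(ncol(p))
    rsrc <- rs + di; csrc <- cs + dj
    ok_r <- rsrc >= 1 & rsrc <= nrow(p)
    ok_c <- csrc >= 1 & csrc <= ncol(p)
    num[rs[ok_r], cs[ok_c]] <- num[rs[ok_r], cs[ok_c]] +
      w * pm[rsrc[ok_r], csrc[ok_c], drop = FALSE]
    den[rs[ok_r], cs[ok_c]] <- den[rs[ok_r], cs[ok_c]] +
      w * mask[rsrc[ok_r], csrc[ok_c], drop = FALSE]
  }
  out <- num / den
  out[!mask] <- NA
  out
}

#' Prediction map of a bag
#'
#' Arranges instance class probabilities on the tile grid.
#'
#' @param bag a bag from [make_bags()].
#' @param probs n x 3 instance probabilities aligned with the bag.
#' @return a `prediction_map`: list with `probs` (Gr x Gc x 3 array, NA off
#'   the mask) and `mask` (logical Gr x Gc, TRUE on non-background tiles).
#' @export
prediction_map <- function(bag, probs) {
  gd <- bag$grid_dim
  arr <- array(NA_real_, dim = c(gd[1], gd[2], 3))
  mask <- matrix(FALSE, gd[1], gd[2])
  for (i in seq_len(nrow(bag$coords))) {
    r <- bag$coords[i, 1] + 1L; cc <- bag$coords[i, 2] + 1L
    arr[r, cc, ] <- probs[i, ]
    mask[r, cc] <- TRUE
  }
  structure(list(probs = arr, mask = mask), class = "prediction_map")
}

#' EM-style representative-tile selection
#'
#' Blurs the target-class channel of a prediction map with a 3x3 Gaussian
#' (sigma 1, masked normalization at borders and background) and selects the
#' cells whose blurred score strictly exceeds either the image-level
#' threshold (the top-`image_pct` tail boundary of this map's scores) or the
#' class-level threshold (the top-`class_pct` tail boundary of `class_pool`,
#' the blurred scores pooled over all slides of the class). On a uniform map
#' all cells tie at the threshold and nothing is selected.
#'
#' @param pmap a [prediction_map()].
#' @param target_class class whose channel is blurred and thresholded.
#' @param image_pct,class_pct top-tail fractions for the two thresholds.
#' @param class_pool optional numeric vector of class-pooled blurred scores.
#' @return list with `indices` (selected cell indices in the bag's instance
#'   order is not implied; these are positions in the grid mask ordering),
#'   `coords` (0-based grid coordinates) and `blurred` (the blurred channel).
#' @export
em_select <- function(pmap, target_class = "ADC", image_pct = 0.001,
                      class_pct = 0.0005, class_pool = NULL) {
  stopifnot(inherits(pmap, "prediction_map"))
  if (!any(pmap$mask)) stop("prediction map has an empty mask")
  ci <- match(target_class, CLASS_LEVELS)
  blurred <- masked_blur3(ifelse(pmap$mask, pmap$probs[, , ci], 0), pmap$mask)
  vals <- blurred[pmap$mask]
  thr_img <- quantile(vals, 1 - image_pct, names = FALSE, type = 7)
  thr_cls <- if (!is.null(class_pool))
    quantile(class_pool, 1 - class_pct, names = FALSE, type = 7)
  else
    quantile(vals, 1 - class_pct, names = FALSE, type = 7)
  thr <- min(thr_img, thr_cls)
  sel <- which(pmap$mask & !is.na(blurred) & blurred > thr)
  coords <- cbind(row(pmap$mask)[sel] - 1L, col(pmap$mask)[sel] - 1L)
  list(indices = sel, coords = coords, blurred = blurred,
       thresholds = c(image = thr_img, class = thr_cls))
}

#' Class histogram of a bag
#'
#' Sums instance class probabilities; components lie in [0, n] and add to n.
#'
#' @param probs n x 3 instance probability matrix.
#' @return numeric 3-vector named NC/ADC/SqCC.
#' @export
class_histogram <- function(probs) {
  h <- colSums(probs)
  names(h) <- CLASS_LEVELS
  h
}

#' Bag-level classifier over class histograms
#'
#' Multinomial logistic regression (`nnet::multinom`) or an RBF-kernel SVM
#' (`e1071::svm` with Platt-scaled probabilities), fitted on class-histogram
#' features.
#'
#' @param hists n x 3 matrix of class histograms.
#' @param labels character/factor slide labels.
#' @param kind "LR" or "SVM".
#' @param seed seed (the SVM's probability calibration is randomized).
#' @return a `bag_classifier` with a [predict()] method returning an
#'   n x 3 probability matrix.
#' @export
histogram_bag_classifier <- function(hists, labels, kind = c("LR", "SVM"),
                                     seed = 1L) {
  kind <- match.arg(kind)
  y <- factor(as.character(labels), levels = CLASS_LEVELS)
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("need at least two classes to fit a bag classifier")
  df <- data.frame(h1 = hists[, 1], h2 = hists[, 2], h3 = hists[, 3], y = y)
  fit <- with_seed(derive_seed(seed, paste0("bagclf-", kind)), {
    if (kind == "LR")
      nnet::multinom(y ~ h1 + h2 + h3, data = df, trace = FALSE, maxit = 500)
    else
      e1071::svm(y ~ h1 + h2 + h3, data = df, kernel = "radial",
                 probability = TRUE)
  })
  structure(list(fit = fit, kind = kind, levels = levels(y)),
            class = "bag_classifier")
}

#' @export
predict.bag_classifier <- function(object, newdata, ...) {
  df <- data.frame(h1 = newdata[, 1], h2 = newdata[, 2], h3 = newdata[, 3])
  if (object$kind == "LR") {
    p <- predict(object$fit, newdata = df, type = "probs")
    if (is.null(dim(p))) p <- cbind(1 - p, p)  # two-level fit
    colnames(p) <- object$levels
  } else {
    pr <- predict(object$fit, newdata = df, probability = TRUE)
    p <- attr(pr, "probabilities")
  }
  out <- matrix(0, nrow(df), length(CLASS_LEVELS),
                dimnames = list(NULL, CLASS_LEVELS))
  out[, colnames(p)] <- p
  out
}

#' Max-feature aggregation of a bag
#'
#' Averages the embeddings of the k instances with the highest cancer
#' probability (maximum over the two cancer channels), the feature fed to the
#' random-forest bag model.
#'
#' @param embeddings n x C instance embedding matrix.
#' @param scores n x 3 instance probability matrix aligned with it.
#' @param k instances to average (clipped to bag size).
#' @return numeric vector of length C.
#' @export
maxfeat_aggregate <- function(embeddings, scores, k = 3L) {
  if (nrow(embeddings) == 0) stop("empty bag")
  cancer <- pmax(scores[, 2], scores[, 3])
  sel <- select_topk(cancer, k = k)$indices
  colMeans(embeddings[sel, , drop = FALSE])
}

#' One MIL training epoch
#'
#' Instance selection followed by one optimization pass: every cancer bag
#' contributes its top-k instances by its own class probability, labeled with
#' the slide label; every non-cancer bag contributes k instances sampled
#' uniformly (seeded), labeled NC, which balances the selected set. The
#' selected set is shuffled and consumed in minibatches by Adam.
#'
#' @param model tile classifier (`nn_model`).
#' @param bags training bags.
#' @param slides slide list.
#' @param k instances per bag.
#' @param state Adam state (from a previous epoch, or NULL).
#' @param lr learning rate.
#' @param batch_size minibatch size.
#' @param seed epoch seed (selection subsampling and shuffling).
#' @return list with updated `model`, `state`, `train_loss`, and `selected`
#'   (data.frame slide_id, grid_row, grid_col, label).
#' @export
mil_train_epoch <- function(model, bags, slides, k, state = NULL, lr = 1e-3,
                            batch_size = 8L, seed = 1L) {
  sel <- NULL
  for (b in bags) {
    n <- nrow(b$coords)
    idx <- if (b$label == "NC") {
      with_seed(derive_seed(seed, paste0("nc-sample-", b$slide_id)),
                sample.int(n, min(k, n)))
    } else {
      sc <- score_instances(model, b, slides)$probs
      select_topk(sc, b$label, k)$indices
    }
    sel <- rbind(sel, data.frame(slide_id = b$slide_id,
                                 slide_index = b$slide_index,
                                 grid_row = b$coords[idx, 1],
                                 grid_col = b$coords[idx, 2],
                                 label = b$label))
  }
  if (is.null(sel) || nrow(sel) == 0) stop("empty instance selection")
  perm <- with_seed(derive_seed(seed, "shuffle"), sample.int(nrow(sel)))
  sel <- sel[perm, ]
  if (is.null(state)) state <- adam_init(model)
  total_loss <- 0; nb <- 0
  starts <- seq(1, nrow(sel), by = batch_size)
  for (st in starts) {
    rows <- st:min(st + batch_size - 1, nrow(sel))
    images <- lapply(rows, function(r)
      extract_tile(slides[[sel$slide_index[r]]]$image,
                   sel$grid_row[r], sel$grid_col[r]))
    labels <- match(sel$label[rows], CLASS_LEVELS)
    bg <- nn_batch_grads(model, images, labels)
    if (!is.finite(bg$loss)) stop("non-finite MIL training loss")
    upd <- adam_step(model, state, bg$grads, lr)
    model <- upd$model; state <- upd$state
    total_loss <- total_loss + bg$loss; nb <- nb + 1
  }
  list(model = model, state = state, train_loss = total_loss / nb,
       selected = sel[, c("slide_id", "grid_row", "grid_col", "label")])
}

#' Train a standard top-k MIL classifier
#'
#' Runs [mil_train_epoch()] for `epochs` epochs, evaluating slide-level
#' validation loss (cross-entropy of [infer_bag_max()] against the slide
#' label) after each and keeping the weights with the lowest validation loss.
#'
#' @param model initial tile classifier.
#' @param bags,slides training bags and the slide list.
#' @param val_bags validation bags.
#' @param k instances per bag.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed master seed.
#' @return list with best `model`, `curves`, and the last epoch's `selected`.
#' @export
mil_train <- function(model, bags, slides, val_bags, k = 3L, epochs = 6L,
                      lr = 1e-3, batch_size = 8L, seed = 1L) {
  state <- NULL
  best <- list(loss = Inf, model = model)
  curves <- NULL
  selected <- NULL
  for (e in seq_len(epochs)) {
    ep <- mil_train_epoch(model, bags, slides, k, state, lr, batch_size,
                          seed = derive_seed(seed, paste0("epoch-", e)))
    model <- ep$model; state <- ep$state; selected <- ep$selected
    v <- mil_validate(model, val_bags, slides)
    if (v[["loss"]] < best$loss) best <- list(loss = v[["loss"]], model = model)
    curves <- rbind(curves, data.frame(epoch = e, train_loss = ep$train_loss,
                                       val_loss = v[["loss"]],
                                       val_acc = v[["acc"]]))
  }
  list(model = best$model, curves = curves, selected = selected)
}

# Slide-level validation loss/accuracy by max aggregation.
mil_validate <- function(model, bags, slides) {
  loss <- 0; correct <- 0
  for (b in bags) {
    p <- infer_bag_max(score_instances(model, b, slides)$probs)
    y <- as.numeric(CLASS_LEVELS == b$label)
    loss <- loss + cross_entropy(y, p)
    correct <- correct + as.numeric(unname(which.max(p)) == which.max(y))
  }
  c(loss = loss / length(bags), acc = correct / length(bags))
}
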