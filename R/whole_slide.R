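## Whole-image training and localization.
##
## The whole-slide method feeds an entire (white-padded) slide through the
## backbone in one forward pass -- no tiling -- with a GMP head, so a small
## lesion only has to light up one receptive field to drive the slide-level
## prediction. Localization comes from class activation maps (CAM); MIL
## prediction maps are assembled per tile for comparison. Both heatmaps are
## upscaled to the slide extent with bicubic interpolation.

#' Whole-slide forward pass
#'
#' A single forward pass over the entire image; the input is never tiled.
#'
#' @param model an `nn_model` (GMP or GAP head).
#' @param image H x W x 3 array, 0-255 (a padded slide's `$image` works).
#' @param max_side guard against accidental huge inputs on a desk machine;
#'   raise it explicitly for larger runs.
#' @return list with `probs`, `logits`, `pooled` and `feature_map`.
#' @export
forward_whole <- function(model, image, max_side = 4096L) {
  if (inherits(image, "padded_slide")) image <- image$image
  d <- dim(image)
  if (max(d[1], d[2]) > max_side)
    stop(sprintf(paste0("input side %d exceeds the %d-pixel guard; pass a ",
                        "larger max_side or downscale the slide"),
         max(d[1], d[2]), max_side))
  nn_forward(model, image)
}

#' Train a whole-slide classifier
#'
#' Standard training loop on whole padded slide images with slide-level
#' labels: batches are seeded draws from the training split, optionally
#' augmented; validation loss is evaluated on the validation split each
#' epoch; the lowest-validation-loss weights are returned.
#'
#' @param slides named list of `labeled_slide` objects.
#' @param split a [stratified_split()] result.
#' @param arch executable [architecture_spec()].
#' @param head "GMP" or "GAP".
#' @param cfg a [train_config()].
#' @param augment_color include color jitter in training augmentation
#'   (disable for corpora whose class signal is chromatic).
#' @param use_augmentation apply augmentation at all.
#' @return list with `model` and `curves`.
#' @export
train_whole <- function(slides, split, arch, head = c("GMP", "GAP"), cfg,
                        augment_color = FALSE, use_augmentation = TRUE) {
  head <- match.arg(head)
  model <- nn_init(arch, head = tolower(head), seed = cfg$seed)
  train_slides <- slides[split$train_ids]
  val_slides <- slides[split$val_ids]
  stopifnot(length(train_slides) > 0, length(val_slides) > 0)

  batch_fn <- function(epoch, step) {
    bseed <- derive_seed(cfg$seed, sprintf("batch-%d-%d", epoch, step))
    idx <- with_seed(bseed, sample.int(length(train_slides), cfg$batch_size,
                                       replace = TRUE))
    images <- lapply(seq_along(idx), function(i) {
      img <- train_slides[[idx[i]]]$image
      if (use_augmentation) {
        ap <- random_augmentation_params(
          derive_seed(bseed, paste0("aug-", i)), color = augment_color)
        img <- augment(img, ap)
      }
      img
    })
    labels <- match(vapply(train_slides[idx], function(s) s$label,
                           character(1)), CLASS_LEVELS)
    list(images = images, labels = labels)
  }
  val_fn <- function(m) {
    loss <- 0; correct <- 0
    for (s in val_slides) {
      p <- nn_predict(m, s$image)
      y <- as.numeric(CLASS_LEVELS == s$label)
      loss <- loss + cross_entropy(y, p)
      correct <- correct + as.numeric(unname(which.max(p)) == which.max(y))
    }
    c(loss = loss / length(val_slides), acc = correct / length(val_slides))
  }
  nn_train(model, batch_fn, val_fn, cfg)
}

#' Class activation map
#'
#' heatmap_cell = sum_c w[class, c] * fm[., ., c], min-max normalized to
#' [0, 1] and bicubically upscaled to the slide extent. Valid for any linear
#' head on a pooled feature vector (GAP or GMP); the logit bias shifts every
#' cell equally and cancels in the normalization.
#'
#' @param feature_map final h x w x C activations (from [forward_whole()]).
#' @param dense_weights C x n_classes linear head weight matrix (`model$Wd`).
#' @param class target class name or column index.
#' @param out_shape (H, W) extent of the output heatmap.
#' @return a `heatmap`: list with `values` (H x W in [0, 1]), `class`,
#'   `source = "CAM"`.
#' @export
cam <- function(feature_map, dense_weights, class, out_shape) {
  ci <- if (is.character(class)) match(class, CLASS_LEVELS) else class
  stopifnot(!is.na(ci), ncol(dense_weights) >= ci,
            dim(feature_map)[3] == nrow(dense_weights))
  d <- dim(feature_map)
  hm <- matrix(matrix(feature_map, nrow = d[1] * d[2]) %*% dense_weights[, ci],
               d[1], d[2])
  rng <- range(hm)
  hm <- if (rng[2] > rng[1]) (hm - rng[1]) / (rng[2] - rng[1]) else hm * 0
  up <- resize_bicubic_cpp(hm, out_shape[1], out_shape[2])
  structure(list(values = clip(up, 0, 1),
                 class = if (is.character(class)) class else CLASS_LEVELS[ci],
                 source = "CAM"),
            class = "heatmap")
}

#' MIL prediction heatmap
#'
#' Upscales the tile-grid probabilities of one class bicubically to the slide
#' extent; background cells contribute 0.
#'
#' @param pmap a [prediction_map()].
#' @param class target class name or index.
#' @param out_shape (H, W) extent of the output heatmap.
#' @return a `heatmap` with `source = "MIL"`.
#' @export
mil_heatmap <- function(pmap, class, out_shape) {
  ci <- if (is.character(class)) match(class, CLASS_LEVELS) else class
  grid <- pmap$probs[, , ci]
  grid[!pmap$mask] <- 0
  up <- resize_bicubic_cpp(grid, out_shape[1], out_shape[2])
  structure(list(values = clip(up, 0, 1),
                 class = if (is.character(class)) class else CLASS_LEVELS[ci],
                 source = "MIL"),
            class = "heatmap")
}

#' Pixel-level localization overlap
#'
#' Binarizes a heatmap at a threshold and scores it against the lesion mask,
#' restricted to tissue.
#'
#' @param hm a `heatmap` (or a plain numeric matrix).
#' @param lesion_mask logical H x W lesion mask (must be non-empty).
#' @param tissue_mask logical H x W tissue mask.
#' @param threshold binarization threshold in [0, 1].
#' @return named vector (precision, recall); precision is NA when nothing is
#'   predicted positive.
#' @export
localization_overlap <- function(hm, lesion_mask, tissue_mask,
                                 threshold = 0.5) {
  v <- if (inherits(hm, "heatmap")) hm$values else hm
  if (sum(lesion_mask) == 0) stop("empty lesion mask")
  pred <- (v >= threshold) & tissue_mask
  les <- lesion_mask & tissue_mask
  tp <- sum(pred & les)
  c(precision = if (sum(pred) > 0) tp / sum(pred) else NA_real_,
    recall = tp / sum(les))
}
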