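## Synthetic slide corpus.
##
## Emulates the statistical structure of an H&E slide corpus at desk scale:
## pure-white background (255 on all channels, so the ">220" background
## filter applies unambiguously), a textured tissue region, and -- on
## cancerous slides -- a planted lesion region with a class-specific colored
## texture occupying a controlled fraction of the tissue area.

#' Per-class texture parameters
#'
#' Base colors are chosen so that lesion textures are separable from benign
#' tissue on mean channel values alone (the mean-channel distance exceeds the
#' pixel noise sigma by a wide margin), while per-slide jitter of the benign
#' base color emulates staining variation between slides.
#'
#' @param noise_sd per-pixel Gaussian noise standard deviation (0-255 scale).
#' @param blob_px spatial scale of the low-frequency texture blobs, pixels.
#' @param base_jitter per-slide uniform jitter applied to the benign base
#'   color, in 0-255 units.
#' @return a list of texture parameters.
#' @export
texture_params <- function(noise_sd = 10, blob_px = 48, base_jitter = 15) {
  list(base = list(NC = c(205, 170, 190),    # benign tissue, pale pink
                   ADC = c(150, 120, 185),   # adenocarcinoma-like, purple
                   SqCC = c(185, 135, 110)), # squamous-like, brown-red
       noise_sd = noise_sd, blob_px = blob_px, base_jitter = base_jitter)
}

#' Synthetic slide specification
#'
#' @param width_px,height_px slide size in pixels (at least 448, two tiles).
#' @param um_per_px microns per pixel.
#' @param label slide class: "NC", "ADC" or "SqCC".
#' @param tissue_fraction fraction of the image covered by tissue, (0, 1].
#' @param lesion_fraction lesion area as a fraction of tissue area; must be 0
#'   exactly when `label == "NC"` and positive otherwise.
#' @param texture per-class texture parameters, see [texture_params()].
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @param slide_id identifier; autogenerated from the seed when missing.
#' @return a `slide_spec` object.
#' @export
slide_spec <- function(width_px = 512L, height_px = 512L, um_per_px = 2.3,
                       label = c("NC", "ADC", "SqCC"), tissue_fraction = 0.6,
                       lesion_fraction = 0, texture = texture_params(),
                       seed = 1L, slide_id = NULL) {
  label <- match.arg(label)
  if (width_px < 448 || height_px < 448)
    stop("slides must be at least 448 pixels (two tiles) on each side")
  if (tissue_fraction <= 0 || tissue_fraction > 1)
    stop("tissue_fraction must lie in (0, 1]")
  if (lesion_fraction < 0 || lesion_fraction >= 1)
    stop("lesion_fraction must lie in [0, 1)")
  if ((label == "NC") != (lesion_fraction == 0))
    stop("lesion_fraction must be 0 exactly for NC slides and positive otherwise")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 um_per_px = um_per_px, label = label,
                 tissue_fraction = tissue_fraction,
                 lesion_fraction = lesion_fraction, texture = texture,
                 seed = as.integer(seed),
                 slide_id = slide_id %||% sprintf("slide_%s_%06d", label, seed)),
            class = "slide_spec")
}

# Low-frequency Gaussian field: coarse iid normals upsampled bilinearly.
lowfreq_field <- function(h, w, blob_px) {
  gh <- max(3L, ceiling(h / blob_px) + 1L)
  gw <- max(3L, ceiling(w / blob_px) + 1L)
  coarse <- array(rnorm(gh * gw), dim = c(gh, gw, 1))
  resize_bilinear_cpp(coarse, h, w)[, , 1]
}

#' Generate one labeled synthetic slide
#'
#' Tissue is the set of pixels where a low-frequency random field is largest,
#' taken at exactly the requested pixel count; the lesion (for cancerous
#' slides) is the connected-ish region of tissue pixels closest to a random
#' center under a noise-perturbed distance, again at exact pixel count, so
#' the realized lesion-to-tissue ratio matches the spec up to rounding.
#' Background is exactly 255 on all channels.
#'
#' @param spec a [slide_spec()].
#' @return a `labeled_slide`: list with `image` (H x W x 3 integer array,
#'   0-255), `label`, `lesion_mask` and `tissue_mask` (logical H x W),
#'   `um_per_px`, `slide_id` and the realized `lesion_fraction`.
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  h <- spec$height_px; w <- spec$width_px
  tx <- spec$texture
  with_seed(spec$seed, {
    # tissue-field correlation length scales with the slide so tissue forms
    # one or two compact sections (as mounted specimens do) rather than
    # scattered speckle
    field <- lowfreq_field(h, w, max(tx$blob_px * 2, round(min(h, w) / 3)))
    n_tissue <- max(1L, round(spec$tissue_fraction * h * w))
    ord <- order(field, decreasing = TRUE)
    tissue <- matrix(FALSE, h, w)
    tissue[ord[seq_len(n_tissue)]] <- TRUE

    lesion <- matrix(FALSE, h, w)
    if (spec$label != "NC") {
      n_lesion <- max(1L, round(spec$lesion_fraction * n_tissue))
      tidx <- which(tissue)
      center <- tidx[sample.int(length(tidx), 1L)]
      ci <- (center - 1L) %% h + 1L
      cj <- (center - 1L) %/% h + 1L
      rows <- (tidx - 1L) %% h + 1L
      cols <- (tidx - 1L) %/% h + 1L
      dist <- sqrt((rows - ci)^2 + (cols - cj)^2)
      wobble <- lowfreq_field(h, w, tx$blob_px)[tidx] * tx$blob_px / 4
      lesion[tidx[order(dist + wobble)[seq_len(n_lesion)]]] <- TRUE
    }

    img <- array(255, dim = c(h, w, 3))
    jitter <- runif(3, -tx$base_jitter, tx$base_jitter)
    modul <- lowfreq_field(h, w, tx$blob_px)
    for (ch in 1:3) {
      base <- matrix(tx$base$NC[ch] + jitter[ch], h, w)
      if (spec$label != "NC") base[lesion] <- tx$base[[spec$label]][ch]
      plane <- base + modul * tx$noise_sd / 2 +
        matrix(rnorm(h * w, sd = tx$noise_sd), h, w)
      page <- img[, , ch]
      page[tissue] <- clip(round(plane[tissue]), 0, 250)
      img[, , ch] <- page
    }
    storage.mode(img) <- "integer"

    structure(list(image = img, label = spec$label, lesion_mask = lesion,
                   tissue_mask = tissue, um_per_px = spec$um_per_px,
                   slide_id = spec$slide_id,
                   lesion_fraction = sum(lesion) / sum(tissue)),
              class = "labeled_slide")
  })
}

#' Generate a labeled corpus of synthetic slides
#'
#' Produces `n_per_class` slides for each of NC, ADC and SqCC. A quota of the
#' cancerous slides is generated in the small-lesion regime (lesion fraction
#' below 0.10 of tissue area); the rest draw lesion fractions from the upper
#' part of `lesion_fraction_range`. Per-slide seeds are derived from the
#' corpus seed, so the corpus is bit-reproducible.
#'
#' @param n_per_class slides per class (>= 1).
#' @param lesion_fraction_range range of lesion-to-tissue area fractions for
#'   cancerous slides; the sub-range below 0.10 is the small-lesion regime.
#' @param small_lesion_quota fraction of cancerous slides (per class, rounded)
#'   drawn from the small-lesion regime; in [0, 1].
#' @param size_px slide side length in pixels.
#' @param seed corpus seed.
#' @param tissue_fraction_range per-slide tissue fraction range.
#' @param texture see [texture_params()].
#' @return list of `labeled_slide` objects.
#' @export
generate_corpus <- function(n_per_class, lesion_fraction_range = c(0.02, 0.35),
                            small_lesion_quota = 0.3, size_px = 512L, seed = 1L,
                            tissue_fraction_range = c(0.4, 0.7),
                            texture = texture_params()) {
  stopifnot(n_per_class >= 1)
  if (small_lesion_quota < 0 || small_lesion_quota > 1)
    stop("small_lesion_quota must lie in [0, 1]")
  lo <- lesion_fraction_range[1]; hi <- lesion_fraction_range[2]
  stopifnot(lo > 0, hi > lo)
  n_small <- round(small_lesion_quota * n_per_class)
  slides <- list()
  for (label in CLASS_LEVELS) {
    for (i in seq_len(n_per_class)) {
      id <- sprintf("%s_%03d", label, i)
      sseed <- derive_seed(seed, paste0("slide-", id))
      lf <- 0
      if (label != "NC") {
        with_seed(derive_seed(seed, paste0("frac-", id)), {
          # a small margin on either side of the 10% rule keeps the realized
          # pixel-count ratio on the intended side of the threshold
          lf <- if (i <= n_small)
            runif(1, lo, min(hi, 0.095))
          else
            runif(1, max(lo, 0.105), hi)
        })
      }
      tf <- with_seed(derive_seed(seed, paste0("tissue-", id)),
                      runif(1, tissue_fraction_range[1], tissue_fraction_range[2]))
      sp <- slide_spec(width_px = size_px, height_px = size_px, label = label,
                       tissue_fraction = tf, lesion_fraction = lf,
                       texture = texture, seed = sseed, slide_id = id)
      slides[[id]] <- generate_slide(sp)
    }
  }
  slides
}

#' Stratified train/validation/test split
#'
#' Slides are stratified by label; within each stratum the split sizes are
#' the largest-remainder rounding of the requested fractions and membership
#' is a seeded random shuffle. Strata with fewer items than non-empty splits
#' are assigned to the training set with a warning.
#'
#' @param slides list of `labeled_slide` objects (or any objects with
#'   `slide_id` and `label` fields).
#' @param fractions numeric (train, val, test), summing to 1.
#' @param seed integer seed.
#' @return a `dataset_split`: list of `train_ids`, `val_ids`, `test_ids`.
#' @export
stratified_split <- function(slides, fractions = c(0.5, 0.1, 0.4), seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8,
            all(fractions >= 0))
  ids <- vapply(slides, function(s) s$slide_id, character(1))
  labels <- vapply(slides, function(s) s$label, character(1))
  out <- list(train_ids = character(0), val_ids = character(0),
              test_ids = character(0))
  n_splits <- sum(fractions > 0)
  for (lab in unique(labels)) {
    sids <- ids[labels == lab]
    n <- length(sids)
    if (n < n_splits) {
      warning(sprintf("stratum '%s' has %d item(s); assigning all to train",
                      lab, n))
      out$train_ids <- c(out$train_ids, sids)
      next
    }
    counts <- largest_remainder(n, fractions)
    perm <- with_seed(derive_seed(seed, paste0("split-", lab)),
                      sample(sids, n))
    out$train_ids <- c(out$train_ids, perm[seq_len(counts[1])])
    if (counts[2] > 0)
      out$val_ids <- c(out$val_ids, perm[counts[1] + seq_len(counts[2])])
    if (counts[3] > 0)
      out$test_ids <- c(out$test_ids, perm[counts[1] + counts[2] + seq_len(counts[3])])
  }
  structure(out, class = "dataset_split")
}

# Largest-remainder apportionment of n items among fractions; ties go to the
# earlier split so the result is deterministic.
largest_remainder <- function(n, fractions) {
  q <- n * fractions
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    pick <- order(q - base, seq_along(q), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(left)]
    base[pick] <- base[pick] + 1
  }
  as.integer(base)
}

#' Is a slide in the small-lesion regime?
#'
#' TRUE iff the slide is cancerous and its lesion area is strictly below 10%
#' of its tissue area. Benign slides return FALSE: the 10% rule applies only
#' to cancerous slides (benign slides join the small-lesion evaluation subset
#' unconditionally, see [small_lesion_subset()]).
#'
#' @param slide a `labeled_slide`.
#' @return logical.
#' @export
is_small_lesion <- function(slide) {
  if (sum(slide$tissue_mask) == 0) stop("slide has an empty tissue mask")
  if (slide$label == "NC") return(FALSE)
  sum(slide$lesion_mask) / sum(slide$tissue_mask) < 0.10
}

#' Small-lesion evaluation subset
#'
#' Cancerous slides with lesion area below 10% of tissue area, plus all
#' benign slides.
#'
#' @param slides list of `labeled_slide` objects.
#' @return the subset, as a list.
#' @export
small_lesion_subset <- function(slides) {
  keep <- vapply(slides, function(s) s$label == "NC" || is_small_lesion(s),
                 logical(1))
  slides[keep]
}
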