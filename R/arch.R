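#' Layer specification
#'
#' Describes one layer on the single downsampling path of a convolutional
#' backbone, carrying just what the receptive-field and shape calculus needs:
#' kernel size, stride and dilation. Padding is always the 'same' (ceil)
#' convention, chosen so a 224-pixel input maps to a 7-cell feature map
#' through five stride-2 stages.
#'
#' @param kind one of "conv", "pool", "identity".
#' @param k kernel size (>= 1).
#' @param s stride (>= 1).
#' @param dilation dilation factor, default 1.
#' @param channels output channels (used only by executable backbones).
#' @return a `layer_spec` object.
#' @export
layer_spec <- function(kind = c("conv", "pool", "identity"),
                       k = 1L, s = 1L, dilation = 1L, channels = NA_integer_) {
  kind <- match.arg(kind)
  stopifnot(k >= 1, s >= 1, dilation >= 1)
  structure(list(kind = kind, k = as.integer(k), s = as.integer(s),
                 dilation = as.integer(dilation),
                 channels = as.integer(channels)),
            class = "layer_spec")
}

#' Architecture specification
#'
#' An ordered list of [layer_spec()]s along the downsampling path, plus the
#' channel count of the final feature map. Parallel residual branches are
#' represented by their longest (main) path: the receptive field of a
#' residual stage is the maximum over branches, and the 1x1/3x3/1x1 main
#' path of a bottleneck block always dominates the identity shortcut.
#'
#' @param layers list of [layer_spec()] objects.
#' @param final_channels channels of the final feature map.
#' @return an `architecture_spec` object.
#' @export
architecture_spec <- function(layers, final_channels) {
  stopifnot(length(layers) >= 1,
            all(vapply(layers, inherits, logical(1), "layer_spec")))
  structure(list(layers = layers, final_channels = as.integer(final_channels)),
            class = "architecture_spec")
}

#' Reference ResNet-50 downsampling path
#'
#' Encodes the published ResNet-50 geometry used as the reference backbone:
#' 7x7/2 stem convolution, 3x3/2 max pool, then bottleneck stages of
#' 3/4/6/3 blocks. Downsampling inside a stage happens on the first 1x1
#' convolution of its first block (the original bottleneck layout); the 3x3
#' convolutions are stride 1. Under the receptive-field recurrence this
#' layout yields a 483-pixel receptive field and a 7-cell output side for a
#' 224-pixel input.
#'
#' @return an [architecture_spec()] with 2048 final channels.
#' @export
resnet50_spec <- function() {
  layers <- list(layer_spec("conv", k = 7, s = 2, channels = 64),
                 layer_spec("pool", k = 3, s = 2))
  blocks <- c(3L, 4L, 6L, 3L)
  strides <- c(1L, 2L, 2L, 2L)
  chans <- c(256L, 512L, 1024L, 2048L)
  for (st in seq_along(blocks)) {
    for (b in seq_len(blocks[st])) {
      s1 <- if (b == 1L) strides[st] else 1L
      layers <- c(layers, list(
        layer_spec("conv", k = 1, s = s1, channels = chans[st] / 4),
        layer_spec("conv", k = 3, s = 1, channels = chans[st] / 4),
        layer_spec("conv", k = 1, s = 1, channels = chans[st])))
    }
  }
  architecture_spec(layers, final_channels = 2048L)
}

#' Compact executable backbone for desk-scale experiments
#'
#' A small strided convolution stack (total downsampling 32, matching the
#' reference backbone) that the in-package network engine can train on a CPU.
#' All algorithms in the package are architecture-agnostic; this spec merely
#' sets the problem size.
#'
#' @param channels output channels per convolution.
#' @return an [architecture_spec()].
#' @export
desk_arch <- function(channels = c(8L, 16L, 24L, 32L)) {
  stopifnot(length(channels) >= 2)
  ks <- c(7L, rep(3L, length(channels) - 1L))
  ss <- c(4L, rep(2L, length(channels) - 1L))
  layers <- Map(function(k, s, ch) layer_spec("conv", k = k, s = s, channels = ch),
                ks, ss, as.integer(channels))
  architecture_spec(unname(layers), final_channels = channels[length(channels)])
}

#' Receptive field of the final feature map
#'
#' Runs the standard recurrence along the downsampling path: starting from
#' r = 1, j = 1, each layer updates r <- r + (k - 1) * dilation * j and
#' j <- j * s, where j is the input-pixel spacing (jump) between adjacent
#' feature-map cells. Residual branches contribute through the longest path,
#' which is the path encoded in the spec.
#'
#' @param arch an [architecture_spec()].
#' @return list with `rf_px` (side length in input pixels) and `jump_px`.
#' @export
receptive_field <- function(arch) {
  stopifnot(inherits(arch, "architecture_spec"))
  r <- 1; j <- 1
  for (ly in arch$layers) {
    r <- r + (ly$k - 1) * ly$dilation * j
    j <- j * ly$s
  }
  list(rf_px = as.integer(r), jump_px = as.integer(j))
}

#' Spatial side of the final feature map
#'
#' Applies the 'same'-padding shape rule out = ceiling(in / s) through every
#' layer of the path.
#'
#' @param arch an [architecture_spec()].
#' @param input_side input side length in pixels.
#' @return integer side length of the final feature map.
#' @export
output_spatial_size <- function(arch, input_side) {
  stopifnot(inherits(arch, "architecture_spec"), input_side >= 1)
  side <- as.integer(input_side)
  for (ly in arch$layers) {
    side <- as.integer(ceiling(side / ly$s))
    if (side < 1) stop("feature map collapsed to zero size")
  }
  side
}

#' Physical receptive field
#'
#' @param rf_px receptive-field side in pixels.
#' @param um_per_px microns per pixel at the working magnification.
#' @return side length in microns, rounded to the nearest micron.
#' @export
physical_receptive_field <- function(rf_px, um_per_px) {
  stopifnot(rf_px > 0, um_per_px > 0)
  round(rf_px * um_per_px)
}

#' Global average pooling
#'
#' Channel-wise arithmetic mean over the spatial extent of an h x w x C
#' feature map.
#'
#' @param fm numeric 3-d array (h, w, C).
#' @return numeric vector of length C.
#' @export
gap <- function(fm) {
  stopifnot(length(dim(fm)) == 3)
  colMeans(matrix(fm, nrow = dim(fm)[1] * dim(fm)[2]))
}

#' Global max pooling
#'
#' Channel-wise maximum over the spatial extent; elementwise `gmp(fm) >=
#' gap(fm)` always, with equality on constant maps.
#'
#' @param fm numeric 3-d array (h, w, C).
#' @return numeric vector of length C.
#' @export
gmp <- function(fm) {
  stopifnot(length(dim(fm)) == 3)
  apply(matrix(fm, nrow = dim(fm)[1] * dim(fm)[2]), 2, max)
}

#' Three-class categorical cross-entropy
#'
#' L = -sum_c y_c log(p_c) with predicted probabilities clipped to
#' [1e-12, 1] before the logarithm so saturated predictions stay finite.
#'
#' @param y one-hot numeric vector.
#' @param y_hat predicted class probabilities (same length, sums to 1).
#' @return non-negative loss; 0 iff the true class has probability 1.
#' @export
cross_entropy <- function(y, y_hat) {
  if (length(y) != length(y_hat) || sum(y == 1) != 1 || sum(y == 0) != length(y) - 1)
    stop("y must be a one-hot vector matching y_hat")
  -sum(y * log(clip(y_hat, 1e-12, 1)))
}
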