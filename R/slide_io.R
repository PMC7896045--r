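## Slide loading, downscaling, white padding, tiling, background filtering
## and the augmentation pipeline.
##
## Conventions: images are H x W x 3 arrays on the 0-255 scale; padding and
## any area exposed by a geometric transform is white (255), consistent with
## the ">220 on all channels" background rule; tiles are 224 x 224 with
## 0-based grid coordinates mapping back to pixel origin (row*224, col*224).

TILE_PX <- 224L
BG_THRESHOLD <- 220L

#' Read a slide image from PNG or plain TIFF
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return H x W x 3 integer array with values 0-255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", ext))
  if (length(dim(x)) == 2) x <- array(rep(x, 3), dim = c(dim(x), 3))
  x <- x[, , 1:3, drop = FALSE]
  img <- array(as.integer(round(x * 255)), dim = dim(x))
  img
}

#' Write a slide image as PNG
#' @param img H x W x 3 array, 0-255.
#' @param path output path.
#' @export
write_image <- function(img, path) {
  png::writePNG(array(clip(as.numeric(img), 0, 255) / 255, dim = dim(img)),
                path)
  invisible(path)
}

#' Downscale an image by a factor
#'
#' Bilinear resampling to `round(dim * factor)`. When working with physical
#' units, divide `um_per_px` by the factor: a 0.46 um/px scan downscaled by
#' 0.2 becomes 2.3 um/px.
#'
#' @param image H x W x C numeric array.
#' @param factor scale factor in (0, 1].
#' @return downscaled array (integer 0-255 if the input was).
#' @export
downscale <- function(image, factor) {
  stopifnot(factor > 0, factor <= 1)
  if (factor == 1) return(image)
  d <- dim(image)
  oh <- round(d[1] * factor); ow <- round(d[2] * factor)
  if (oh < 1 || ow < 1) stop("downscale factor collapses the image below 1x1")
  out <- resize_bilinear_cpp(array(as.numeric(image), dim = d), oh, ow)
  array(as.integer(round(out)), dim = dim(out))
}

#' Downscale a labeled slide
#'
#' Resamples the image bilinearly, the masks by nearest neighbour, and
#' divides `um_per_px` by the factor (0.46 um/px at x20 downscaled by 0.2
#' becomes 2.3 um/px, the x4 working magnification).
#'
#' @param slide a `labeled_slide`.
#' @param factor scale factor in (0, 1].
#' @return the downscaled `labeled_slide`.
#' @export
downscale_slide <- function(slide, factor) {
  if (factor == 1) return(slide)
  slide$image <- downscale(slide$image, factor)
  d <- dim(slide$image)
  resize_mask <- function(m)
    resize_bilinear_cpp(array(m * 1, dim = c(dim(m), 1)), d[1], d[2])[, , 1] > 0.5
  slide$tissue_mask <- resize_mask(slide$tissue_mask)
  slide$lesion_mask <- resize_mask(slide$lesion_mask)
  slide$um_per_px <- slide$um_per_px / factor
  slide
}

#' Pad an image to a square with white
#'
#' Content is anchored at the top-left origin and the remainder filled with
#' 255, so image/mask alignment is preserved trivially.
#'
#' @param image H x W x 3 array.
#' @param target_side side of the output square; must be >= max(H, W)
#'   (no cropping).
#' @return a `padded_slide`: list with `image` (S x S x 3), `original_shape`
#'   and `fill_value = 255`.
#' @export
pad_to_square <- function(image, target_side) {
  d <- dim(image)
  if (target_side < max(d[1], d[2]))
    stop("target_side smaller than the image; cropping is not supported")
  out <- array(255L, dim = c(target_side, target_side, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- image
  structure(list(image = out, original_shape = d[1:2], fill_value = 255L),
            class = "padded_slide")
}

# Pad on the bottom/right with white so both sides are multiples of `tile`.
pad_to_multiple <- function(image, tile = TILE_PX) {
  d <- dim(image)
  H <- as.integer(ceiling(d[1] / tile) * tile)
  W <- as.integer(ceiling(d[2] / tile) * tile)
  if (H == d[1] && W == d[2]) return(image)
  out <- array(255L, dim = c(H, W, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- image
  out
}

#' Extract one tile from a slide image
#'
#' Pixels beyond the image extent are white, so tiles on the bottom/right
#' border behave as if the slide had been padded.
#'
#' @param image H x W x 3 array.
#' @param grid_row,grid_col 0-based tile grid coordinates.
#' @param tile tile side in pixels.
#' @return tile pixel array (tile x tile x 3, integer).
#' @export
extract_tile <- function(image, grid_row, grid_col, tile = TILE_PX) {
  d <- dim(image)
  r0 <- grid_row * tile; c0 <- grid_col * tile
  out <- array(255L, dim = c(tile, tile, d[3]))
  ri <- seq_len(min(tile, d[1] - r0)); ci <- seq_len(min(tile, d[2] - c0))
  if (length(ri) > 0 && length(ci) > 0)
    out[ri, ci, ] <- image[r0 + ri, c0 + ci, , drop = FALSE]
  out
}

#' Slice a slide into nonoverlapping tiles
#'
#' The image is white-padded to multiples of the tile size; tiles are
#' returned in row-major order and form a disjoint cover of the padded image.
#'
#' @param image H x W x 3 array.
#' @param tile tile side, default 224.
#' @param slide_id carried into each tile.
#' @return list of tiles: each a list with `pixels`, `grid_row`, `grid_col`
#'   (0-based) and `slide_id`.
#' @export
tile_slide <- function(image, tile = TILE_PX, slide_id = "") {
  d <- dim(image)
  gr <- ceiling(d[1] / tile); gc <- ceiling(d[2] / tile)
  tiles <- vector("list", gr * gc)
  n <- 0L
  for (r in seq_len(gr) - 1L) {
    for (cc in seq_len(gc) - 1L) {
      n <- n + 1L
      tiles[[n]] <- list(pixels = extract_tile(image, r, cc, tile),
                         grid_row = r, grid_col = cc, slide_id = slide_id)
    }
  }
  tiles
}

#' Background test for a tile
#'
#' TRUE iff every pixel of every channel is strictly greater than 220.
#' Monotone: raising any pixel value never turns a background tile into
#' tissue.
#'
#' @param tile a tile (list with `pixels`) or a pixel array.
#' @return logical.
#' @export
is_background <- function(tile) {
  px <- if (is.list(tile)) tile$pixels else tile
  all(px > BG_THRESHOLD)
}

#' Filter background tiles from a bag
#'
#' @param tiles list of tiles from [tile_slide()].
#' @return list with `kept` (the non-background tiles) and
#'   `removed_fraction`. Warns when every tile is background.
#' @export
filter_tiles <- function(tiles) {
  stopifnot(length(tiles) > 0)
  bg <- vapply(tiles, is_background, logical(1))
  if (all(bg)) warning("all tiles are background; downstream bag is empty")
  list(kept = tiles[!bg], removed_fraction = mean(bg))
}

#' Augmentation parameters
#'
#' Field ranges follow the reference pipeline: contrast multiplier in
#' [0.5, 1.5], brightness (HSV value) multiplier in [0.65, 1.35], hue and
#' value additions in [-32, 32] on the 0-255 scale. Geometric fields are a
#' horizontal/vertical flip, an integer pixel translation and a rotation in
#' degrees.
#'
#' @param flip_h,flip_v logical flips.
#' @param translation_px integer (dx, dy) = (column, row) shift in pixels.
#' @param rotation_deg rotation about the image centre, degrees.
#' @param contrast,brightness multipliers.
#' @param hue_shift,value_shift additive HSV shifts, integers in [-32, 32].
#' @return an `augmentation_params` object.
#' @export
augmentation_params <- function(flip_h = FALSE, flip_v = FALSE,
                                translation_px = c(0L, 0L), rotation_deg = 0,
                                contrast = 1, brightness = 1,
                                hue_shift = 0L, value_shift = 0L) {
  if (contrast < 0.5 || contrast > 1.5) stop("contrast outside [0.5, 1.5]")
  if (brightness < 0.65 || brightness > 1.35)
    stop("brightness outside [0.65, 1.35]")
  if (abs(hue_shift) > 32) stop("hue_shift outside [-32, 32]")
  if (abs(value_shift) > 32) stop("value_shift outside [-32, 32]")
  structure(list(flip_h = flip_h, flip_v = flip_v,
                 translation_px = as.integer(translation_px),
                 rotation_deg = rotation_deg, contrast = contrast,
                 brightness = brightness, hue_shift = as.integer(hue_shift),
                 value_shift = as.integer(value_shift)),
            class = "augmentation_params")
}

#' Draw random augmentation parameters
#'
#' Samples uniformly from the allowed ranges (or narrower ones). `color = FALSE`
#' fixes all color fields at identity, leaving flips/translation/rotation;
#' useful for corpora whose class signal is itself chromatic.
#'
#' @param seed integer seed.
#' @param max_translation_px maximum absolute shift per axis.
#' @param rotations set of rotation angles sampled from.
#' @param color draw color parameters too?
#' @return an [augmentation_params()] object.
#' @export
random_augmentation_params <- function(seed, max_translation_px = 16L,
                                       rotations = c(0, 90, 180, 270),
                                       color = TRUE) {
  with_seed(seed, {
    tr <- sample(seq(-max_translation_px, max_translation_px), 2, replace = TRUE)
    augmentation_params(
      flip_h = runif(1) < 0.5, flip_v = runif(1) < 0.5,
      translation_px = tr, rotation_deg = sample(rotations, 1),
      contrast = if (color) runif(1, 0.5, 1.5) else 1,
      brightness = if (color) runif(1, 0.65, 1.35) else 1,
      hue_shift = if (color) sample(-32:32, 1) else 0L,
      value_shift = if (color) sample(-32:32, 1) else 0L)
  })
}

# 0-255 RGB -> HSV with h, s in [0, 1], v in [0, 255].
rgb_to_hsv255 <- function(r, g, b) {
  hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                            maxColorValue = 255)
  list(h = hsv[1, ], s = hsv[2, ], v = hsv[3, ] * 255)
}

# Inverse of rgb_to_hsv255, vectorized numerically.
hsv255_to_rgb <- function(h, s, v) {
  i <- floor(h * 6) %% 6
  f <- h * 6 - floor(h * 6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Apply an augmentation to an image
#'
#' Deterministic given the parameters. Pipeline order: horizontal flip,
#' vertical flip, translation, rotation (exposed area filled white), then
#' contrast (RGB deviations scaled about the per-image mean), brightness
#' (multiplies HSV value), hue shift (wraps modulo 256) and value shift
#' (clips to [0, 255]). Identity parameters return the image unchanged.
#'
#' @param image H x W x 3 array, 0-255.
#' @param params an [augmentation_params()].
#' @return augmented image, integer 0-255, same shape.
#' @export
augment <- function(image, params) {
  stopifnot(inherits(params, "augmentation_params"))
  img <- array(as.numeric(image), dim = dim(image))
  d <- dim(img)
  if (params$flip_h) img <- img[, d[2]:1, , drop = FALSE]
  if (params$flip_v) img <- img[d[1]:1, , , drop = FALSE]
  tr <- params$translation_px
  if (any(tr != 0L)) {
    out <- array(255, dim = d)
    src_r <- seq_len(d[1]) - tr[2]
    src_c <- seq_len(d[2]) - tr[1]
    ok_r <- src_r >= 1 & src_r <= d[1]
    ok_c <- src_c >= 1 & src_c <= d[2]
    out[which(ok_r), which(ok_c), ] <- img[src_r[ok_r], src_c[ok_c], , drop = FALSE]
    img <- out
  }
  if (params$rotation_deg != 0)
    img <- rotate_bilinear_cpp(img, params$rotation_deg, 255)
  if (params$contrast != 1) {
    m <- mean(img)
    img <- clip(m + (img - m) * params$contrast, 0, 255)
  }
  if (params$brightness != 1 || params$hue_shift != 0L || params$value_shift != 0L) {
    hsv <- rgb_to_hsv255(img[, , 1], img[, , 2], img[, , 3])
    h <- (hsv$h * 256 + params$hue_shift) %% 256 / 256
    v <- clip(hsv$v * params$brightness + params$value_shift, 0, 255)
    rgb <- hsv255_to_rgb(h, hsv$s, v)
    img <- array(c(rgb$r, rgb$g, rgb$b), dim = d)
  }
  array(as.integer(round(clip(img, 0, 255))), dim = d)
}
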