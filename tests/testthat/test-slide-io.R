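# Downscaling, padding, tiling, background filtering and augmentation.

test_that("downscale follows the resize rule", {
  img <- array(100L, dim = c(1000, 800, 3))
  out <- downscale(img, 0.2)
  expect_identical(dim(out)[1:2], c(200L, 160L))
  expect_identical(downscale(img, 1), img)
  expect_error(downscale(array(1L, c(4, 4, 3)), 0.1), "1x1")
})

test_that("slide-level downscaling rescales the pixel pitch", {
  s <- generate_slide(slide_spec(label = "ADC", lesion_fraction = 0.1,
                                 tissue_fraction = 0.5, seed = 3,
                                 um_per_px = 0.46,
                                 width_px = 448, height_px = 448))
  d <- downscale_slide(s, 0.2)
  expect_equal(d$um_per_px, 2.3)  # x20 scan pitch -> x4 working pitch
  expect_identical(dim(d$image)[1:2], c(90L, 90L))
  expect_lt(abs(mean(d$tissue_mask) - mean(s$tissue_mask)), 0.05)
})

test_that("bilinear resampling matches a hand-computed case", {
  # 1-D ramp [0, 2] upscaled 2x with half-pixel centres: [0, 0.5, 1.5, 2]
  out <- wsiweak:::resize_bilinear_cpp(array(c(0, 2), dim = c(2, 1, 1)), 4, 1)
  expect_equal(as.numeric(out), c(0, 0.5, 1.5, 2))
})

test_that("pad_to_square anchors content at the origin with white fill", {
  img <- array(7L, dim = c(100, 80, 3))
  p <- pad_to_square(img, 128)
  expect_identical(dim(p$image), c(128L, 128L, 3L))
  expect_identical(p$image[1:100, 1:80, ], img)
  expect_true(all(p$image[101:128, , ] == 255L))
  expect_true(all(p$image[, 81:128, ] == 255L))
  sq <- array(3L, dim = c(64, 64, 3))
  p2 <- pad_to_square(sq, 64)
  expect_identical(p2$image, sq)
  expect_error(pad_to_square(img, 90), "cropping")
})

test_that("tiling partitions the padded image and reconstructs it", {
  img <- array(sample.int(250, 448 * 448 * 3, replace = TRUE),
               dim = c(448, 448, 3))
  tiles <- tile_slide(img)
  expect_length(tiles, 4)
  img2 <- array(1L, dim = c(448, 672, 3))
  t2 <- tile_slide(img2)
  expect_length(t2, 6)
  expect_identical(max(vapply(t2, `[[`, integer(1), "grid_row")), 1L)
  expect_identical(max(vapply(t2, `[[`, integer(1), "grid_col")), 2L)

  recon <- array(0L, dim = c(448, 448, 3))
  for (t in tiles)
    recon[t$grid_row * 224 + 1:224, t$grid_col * 224 + 1:224, ] <- t$pixels
  expect_identical(recon, img)
})

test_that("background rule is strict at the 220 boundary and monotone", {
  expect_true(is_background(array(255L, c(224, 224, 3))))
  expect_true(is_background(array(221L, c(224, 224, 3))))
  px <- array(255L, c(224, 224, 3)); px[17, 3, 2] <- 220L
  expect_false(is_background(px))
  # monotone: raising values never flips TRUE -> FALSE
  withr::with_seed(2, {
    for (r in 1:20) {
      tile <- array(sample(200:255, 48, replace = TRUE), dim = c(4, 4, 3))
      raised <- pmin(tile + sample(0:30, 1), 255L)
      if (is_background(tile)) expect_true(is_background(raised))
    }
  })
})

test_that("filter_tiles reports the removed fraction", {
  bg <- list(pixels = array(255L, c(224, 224, 3)))
  fg <- list(pixels = array(100L, c(224, 224, 3)))
  res <- filter_tiles(c(rep(list(bg), 8), rep(list(fg), 2)))
  expect_length(res$kept, 2)
  expect_equal(res$removed_fraction, 0.8)
  res2 <- filter_tiles(list(fg, fg))
  expect_equal(res2$removed_fraction, 0)
  expect_warning(filter_tiles(list(bg)), "background")
})

test_that("background removal on a sparse-tissue slide approaches the production rate", {
  s <- generate_slide(slide_spec(width_px = 3360, height_px = 3360,
                                 label = "NC", tissue_fraction = 0.2,
                                 lesion_fraction = 0, seed = 4))
  f <- filter_tiles(tile_slide(s$image))
  expect_lt(abs(f$removed_fraction - 0.8), 0.1)
})

test_that("augmentation is deterministic, involutive for flips, and validated", {
  img <- toy_tile(1, seed = 5, side = 48)
  ident <- augmentation_params()
  expect_identical(augment(img, ident), array(as.integer(round(img)), dim(img)))
  fl <- augmentation_params(flip_h = TRUE)
  expect_identical(augment(augment(img, fl), fl),
                   array(as.integer(round(img)), dim(img)))
  pr <- random_augmentation_params(seed = 9)
  a1 <- augment(img, pr); a2 <- augment(img, pr)
  expect_identical(a1, a2)
  expect_identical(dim(a1), dim(img))
  expect_true(is.integer(a1))
  expect_error(augmentation_params(contrast = 2), "contrast")
  expect_error(augmentation_params(hue_shift = 40), "hue")
  # exposed areas from translation are white
  tshift <- augmentation_params(translation_px = c(10L, 6L))
  at <- augment(img, tshift)
  expect_true(all(at[1:6, , ] == 255L))
  expect_true(all(at[, 1:10, ] == 255L))
})

test_that("images survive a PNG round trip", {
  dir <- withr::local_tempdir()
  img <- array(sample(0:255, 64 * 64 * 3, replace = TRUE), dim = c(64, 64, 3))
  storage.mode(img) <- "integer"
  p <- file.path(dir, "x.png")
  write_image(img, p)
  expect_identical(read_image(p), img)
})
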