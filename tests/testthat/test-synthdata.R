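# Synthetic slide generator, corpus, split, and small-lesion rules.

test_that("spec invariants are enforced", {
  expect_error(slide_spec(label = "NC", lesion_fraction = 0.1), "NC")
  expect_error(slide_spec(label = "ADC", lesion_fraction = 0), "NC")
  expect_error(slide_spec(width_px = 300), "448")
  expect_error(slide_spec(tissue_fraction = 0), "tissue_fraction")
  expect_error(slide_spec(label = "ADC", lesion_fraction = 1), "lesion_fraction")
})

test_that("generation is deterministic and respects masks and background", {
  sp <- slide_spec(label = "NC", tissue_fraction = 0.5, seed = 1,
                   width_px = 448, height_px = 448)
  s1 <- generate_slide(sp); s2 <- generate_slide(sp)
  expect_identical(s1$image, s2$image)
  expect_false(any(s1$lesion_mask))
  bg <- !s1$tissue_mask
  for (ch in 1:3) expect_true(all(s1$image[, , ch][bg] == 255L))
  expect_true(all(s1$lesion_mask | !s1$lesion_mask))  # lesion subset of tissue:
  expect_true(all(!s1$lesion_mask | s1$tissue_mask))
})

test_that("realized lesion fraction tracks the requested fraction", {
  s <- generate_slide(slide_spec(label = "ADC", lesion_fraction = 0.05,
                                 tissue_fraction = 0.6, seed = 7))
  ratio <- sum(s$lesion_mask) / sum(s$tissue_mask)
  expect_gte(ratio, 0.045); expect_lte(ratio, 0.055)

  # across many seeded slides the relative error stays below 10%
  for (sd in 1:50) {
    lf <- 0.02 + (sd %% 10) * 0.03
    sl <- generate_slide(slide_spec(label = "SqCC", lesion_fraction = lf,
                                    tissue_fraction = 0.5, seed = sd,
                                    width_px = 448, height_px = 448))
    expect_lt(abs(sl$lesion_fraction - lf) / lf, 0.10)
  }
})

test_that("lesion texture is separable from benign tissue at depth 0", {
  s <- generate_slide(slide_spec(label = "ADC", lesion_fraction = 0.3,
                                 tissue_fraction = 0.7, seed = 11))
  les <- which(s$lesion_mask); ben <- which(s$tissue_mask & !s$lesion_mask)
  mean_ch <- function(idx) sapply(1:3, function(ch) mean(s$image[, , ch][idx]))
  # mean-channel distance exceeds the pixel-noise sigma (10)
  expect_gt(sqrt(sum((mean_ch(les) - mean_ch(ben))^2)), 10)

  # depth-0 nearest-mean classifier on 32x32 patch mean colors
  patch_feats <- function(idx_mask) {
    feats <- NULL
    for (r in seq(1, 512 - 31, by = 32)) for (cc in seq(1, 512 - 31, by = 32)) {
      m <- idx_mask[r:(r + 31), cc:(cc + 31)]
      t <- s$tissue_mask[r:(r + 31), cc:(cc + 31)]
      if (mean(t) > 0.9) {
        lab <- if (mean(m[t]) > 0.5) 1L else 0L
        feats <- rbind(feats, c(sapply(1:3, function(ch)
          mean(s$image[r:(r + 31), cc:(cc + 31), ch])), lab))
      }
    }
    feats
  }
  f <- patch_feats(s$lesion_mask)
  mu1 <- colMeans(f[f[, 4] == 1, 1:3, drop = FALSE])
  mu0 <- colMeans(f[f[, 4] == 0, 1:3, drop = FALSE])
  pred <- apply(f[, 1:3], 1, function(v)
    as.integer(sum((v - mu1)^2) < sum((v - mu0)^2)))
  expect_gt(mean(pred == f[, 4]), 0.9)
})

test_that("corpus honors class balance, quota and reproducibility", {
  corpus <- generate_corpus(10, size_px = 448, small_lesion_quota = 0.5,
                            seed = 3)
  labels <- vapply(corpus, function(s) s$label, character(1))
  expect_equal(unname(table(labels)[c("NC", "ADC", "SqCC")]),
               rep(10L, 3), ignore_attr = TRUE)
  cancers <- corpus[labels != "NC"]
  small <- vapply(cancers, is_small_lesion, logical(1))
  expect_identical(sum(small), 10L)

  corpus0 <- generate_corpus(4, size_px = 448, small_lesion_quota = 0,
                             seed = 5)
  cancers0 <- Filter(function(s) s$label != "NC", corpus0)
  expect_false(any(vapply(cancers0, is_small_lesion, logical(1))))

  corpus_b <- generate_corpus(4, size_px = 448, small_lesion_quota = 0,
                              seed = 5)
  expect_identical(names(corpus0), names(corpus_b))
  expect_identical(corpus0[[5]]$image, corpus_b[[5]]$image)
  expect_error(generate_corpus(4, small_lesion_quota = 1.2), "quota")
})

test_that("stratified split reproduces the reference 5045/561/1397 allocation", {
  counts <- c(NC = 2039L, ADC = 3876L, SqCC = 1088L)
  slides <- list(); i <- 0
  for (lab in names(counts)) for (k in seq_len(counts[[lab]])) {
    i <- i + 1
    slides[[i]] <- list(slide_id = sprintf("s%05d", i), label = lab)
  }
  sp <- stratified_split(slides, c(5045, 561, 1397) / 7003, seed = 9)
  expect_length(sp$train_ids, 5045)
  expect_length(sp$val_ids, 561)
  expect_length(sp$test_ids, 1397)
  # frozen per-stratum largest-remainder counts
  labs <- setNames(vapply(slides, function(s) s$label, character(1)),
                   vapply(slides, function(s) s$slide_id, character(1)))
  expect_equal(unname(table(labs[sp$train_ids])[c("NC", "ADC", "SqCC")]),
               c(1469L, 2792L, 784L), ignore_attr = TRUE)
  expect_equal(unname(table(labs[sp$val_ids])[c("NC", "ADC", "SqCC")]),
               c(163L, 311L, 87L), ignore_attr = TRUE)
  expect_equal(unname(table(labs[sp$test_ids])[c("NC", "ADC", "SqCC")]),
               c(407L, 773L, 217L), ignore_attr = TRUE)
})

test_that("split preserves class proportions and handles edge cases", {
  slides <- list()
  for (lab in c("NC", "ADC", "SqCC")) for (k in 1:10)
    slides[[paste0(lab, k)]] <- list(slide_id = paste0(lab, k), label = lab)
  sp <- stratified_split(slides, c(0.6, 0.2, 0.2), seed = 4)
  labs <- setNames(rep(c("NC", "ADC", "SqCC"), each = 10),
                   names(slides))
  for (ids in list(sp$train_ids, sp$val_ids, sp$test_ids))
    expect_true(all(table(labs[ids]) == length(ids) / 3))
  # disjoint and complete
  all_ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
  expect_setequal(all_ids, names(slides))
  expect_false(anyDuplicated(all_ids) > 0)

  three <- list(list(slide_id = "a", label = "NC"),
                list(slide_id = "b", label = "ADC"),
                list(slide_id = "c", label = "SqCC"))
  sp1 <- stratified_split(three, c(1, 0, 0), seed = 1)
  expect_setequal(sp1$train_ids, c("a", "b", "c"))

  expect_warning(stratified_split(list(list(slide_id = "a", label = "NC")),
                                  c(0.4, 0.3, 0.3), seed = 1),
                 "train")
})

test_that("small-lesion rule is strict and label-gated", {
  expect_true(is_small_lesion(fake_slide("a", "ADC", lesion_px = 9)))
  expect_false(is_small_lesion(fake_slide("b", "SqCC", lesion_px = 10)))
  expect_false(is_small_lesion(fake_slide("c", "NC", lesion_px = 0)))
  empty <- fake_slide("d", "ADC", lesion_px = 1, tissue_px = 0)
  empty$tissue_mask[] <- FALSE
  expect_error(is_small_lesion(empty), "tissue")

  slides <- list(fake_slide("a", "ADC", 9), fake_slide("b", "ADC", 50),
                 fake_slide("c", "NC"), fake_slide("d", "SqCC", 5))
  sub <- small_lesion_subset(slides)
  expect_setequal(vapply(sub, `[[`, character(1), "slide_id"),
                  c("a", "c", "d"))
})

test_that("slides round-trip through PNG + JSON sidecar", {
  dir <- withr::local_tempdir()
  s <- generate_slide(slide_spec(label = "ADC", lesion_fraction = 0.1,
                                 tissue_fraction = 0.5, seed = 2,
                                 width_px = 448, height_px = 448))
  write_slide(s, dir)
  r <- read_slide(dir, s$slide_id)
  expect_identical(r$image, s$image)
  expect_identical(r$lesion_mask, s$lesion_mask)
  expect_identical(r$label, "ADC")
  expect_equal(r$lesion_fraction, s$lesion_fraction)
  mf <- corpus_manifest(list(s))
  expect_equal(nrow(mf), 1)
  expect_identical(mf$label, "ADC")
})
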