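# MIL baselines: top-k selection, max aggregation, EM selection, histogram
# classifiers, max-feature aggregation, recurrent aggregation, MIL training.

test_that("top-k selection matches exhaustive sorting, ties and clipping", {
  expect_identical(select_topk(c(0.1, 0.9, 0.5), k = 1)$indices, 2L)
  expect_setequal(select_topk(c(0.4, 0.6), k = 3)$indices, 1:2)
  tie <- c(0.1, 0.2, 0.7, 0.3, 0.1, 0.7)
  expect_identical(select_topk(tie, k = 1)$indices, 3L)

  withr::with_seed(10, {
    for (r in 1:50) {
      n <- sample(1:20, 1); k <- sample(1:6, 1)
      s <- round(runif(n), 2)  # rounding forces frequent ties
      got <- select_topk(s, k = k)$indices
      want <- order(-s, seq_len(n))[seq_len(min(k, n))]
      expect_identical(got, want)
      expect_false(anyDuplicated(got) > 0)
    }
  })
})

test_that("bag max aggregation matches brute force and is permutation invariant", {
  sc <- cbind(NC = c(0.7, 0.05, 0.5), ADC = c(0.2, 0.9, 0.4),
              SqCC = c(0.1, 0.05, 0.1))
  p <- infer_bag_max(sc)
  # ADC component is the max instance ADC probability before renormalization
  expect_equal(unname(p["ADC"] * (max(0, 1 - 0.9) + 0.9 + max(sc[, 3]))), 0.9)
  withr::with_seed(3, {
    for (r in 1:25) {
      n <- sample(1:12, 1)
      m <- matrix(runif(n * 3), n, 3); m <- m / rowSums(m)
      p1 <- infer_bag_max(m)
      perm <- sample.int(n)
      expect_equal(infer_bag_max(m[perm, , drop = FALSE]), p1)
      # brute-force oracle
      sa <- -Inf; sq <- -Inf
      for (i in seq_len(n)) { sa <- max(sa, m[i, 2]); sq <- max(sq, m[i, 3]) }
      v <- c(max(0, 1 - max(sa, sq)), sa, sq)
      expect_equal(unname(p1), v / sum(v))
    }
  })
  expect_error(infer_bag_max(matrix(numeric(0), 0, 3)), "empty")
})

test_that("masked 3x3 blur reproduces the Gaussian stencil on an impulse", {
  grid <- matrix(0, 5, 5); grid[3, 3] <- 1
  mask <- matrix(TRUE, 5, 5)
  b <- wsiweak:::masked_blur3(grid, mask)
  K <- wsiweak:::gaussian3x3()
  expect_equal(b[2:4, 2:4], K / sum(K))
  expect_equal(b[1, 1], 0)
})

test_that("EM selection thresholds behave on degenerate and hot-cell maps", {
  mk_pmap <- function(vals) {
    g <- dim(vals)[1]
    arr <- array(1 / 3, dim = c(g, g, 3))
    arr[, , 2] <- vals
    structure(list(probs = arr, mask = matrix(TRUE, g, g)),
              class = "prediction_map")
  }
  uni <- mk_pmap(matrix(0.4, 5, 5))
  expect_length(em_select(uni, "ADC", image_pct = 0.1)$indices, 0)

  hot_vals <- matrix(0.1, 5, 5); hot_vals[3, 3] <- 0.9
  sel <- em_select(mk_pmap(hot_vals), "ADC", image_pct = 0.1)
  expect_true(13L %in% sel$indices)  # column-major index of (3, 3)

  # as the image fraction shrinks, only the argmax neighbourhood survives
  sel2 <- em_select(mk_pmap(hot_vals), "ADC", image_pct = 0.02,
                    class_pct = 0.02)
  expect_true(all(sel2$indices %in% sel$indices))
  empty <- structure(list(probs = array(0, c(2, 2, 3)),
                          mask = matrix(FALSE, 2, 2)),
                     class = "prediction_map")
  expect_error(em_select(empty), "mask")
})

test_that("class histograms sum instance probabilities", {
  h <- class_histogram(rbind(c(0.2, 0.5, 0.3), c(0.4, 0.4, 0.2)))
  expect_equal(unname(h), c(0.6, 0.9, 0.5))
  expect_equal(sum(h), 2)
})

test_that("histogram bag classifiers fit separable data identically", {
  withr::with_seed(8, {
    n <- 30
    labs <- rep(c("NC", "ADC", "SqCC"), each = n)
    hists <- rbind(
      cbind(8 + rnorm(n, sd = 0.3), 1 + rnorm(n, sd = 0.3), 1 + rnorm(n, sd = 0.3)),
      cbind(1 + rnorm(n, sd = 0.3), 8 + rnorm(n, sd = 0.3), 1 + rnorm(n, sd = 0.3)),
      cbind(1 + rnorm(n, sd = 0.3), 1 + rnorm(n, sd = 0.3), 8 + rnorm(n, sd = 0.3)))
  })
  lr <- histogram_bag_classifier(hists, labs, "LR", seed = 1)
  sv <- histogram_bag_classifier(hists, labs, "SVM", seed = 1)
  p_lr <- predict(lr, hists); p_sv <- predict(sv, hists)
  cl <- function(p) colnames(p)[max.col(p)]
  expect_equal(mean(cl(p_lr) == labs), 1.0)
  expect_equal(cl(p_lr), cl(p_sv))
  expect_error(histogram_bag_classifier(hists[1:30, ], labs[1:30], "LR"),
               "two classes")
})

test_that("max-feature aggregation equals sort-then-average", {
  withr::with_seed(4, {
    emb <- matrix(rnorm(8 * 5), 8, 5)
    sc <- matrix(runif(24), 8, 3); sc <- sc / rowSums(sc)
    got <- maxfeat_aggregate(emb, sc, k = 3)
    idx <- order(-pmax(sc[, 2], sc[, 3]), 1:8)[1:3]
    expect_equal(got, colMeans(emb[idx, ]))
    expect_equal(maxfeat_aggregate(emb, sc, k = 1),
                 emb[which.max(pmax(sc[, 2], sc[, 3])), ])
    same <- matrix(rep(emb[1, ], each = 8), 8, 5)
    expect_equal(maxfeat_aggregate(same, sc, k = 4), emb[1, ])
  })
})

test_that("recurrent aggregation is deterministic and learns top-1-coded labels", {
  rnn <- rnn_init(6, hidden = 16, seed = 2)
  x <- matrix(rnorm(12), 2, 6)
  expect_equal(rnn_aggregate(rnn, x), rnn_aggregate(rnn, x))
  p1 <- rnn_aggregate(rnn, x[1, , drop = FALSE])
  expect_equal(sum(p1), 1)
  expect_error(rnn_aggregate(rnn, matrix(numeric(0), 0, 6)), "empty")

  withr::with_seed(6, {
    mk <- function(cl) {
      e <- matrix(rnorm(3 * 6, sd = 0.2), 3, 6)
      e[1, cl] <- e[1, cl] + 3  # top instance encodes the class
      e
    }
    cls <- sample(1:3, 120, replace = TRUE)
    seqs <- lapply(cls, mk)
  })
  tr <- rnn_init(6, hidden = 16, seed = 3)
  tr <- rnn_train(tr, seqs[1:90], cls[1:90], epochs = 25, lr = 5e-3, seed = 4)
  pred <- vapply(91:120, function(i) which.max(rnn_aggregate(tr, seqs[[i]])),
                 integer(1))
  expect_gt(mean(pred == cls[91:120]), 0.9)
})

test_that("MIL training is seeded-deterministic and decreases loss on an all-NC corpus", {
  corpus <- lapply(1:3, function(i)
    generate_slide(slide_spec(label = "NC", tissue_fraction = 0.6,
                              seed = 20 + i, width_px = 448, height_px = 448,
                              slide_id = paste0("nc", i))))
  names(corpus) <- vapply(corpus, `[[`, character(1), "slide_id")
  bags <- make_bags(corpus)
  m <- nn_init(tile_arch(), "gap", seed = 1)
  losses <- numeric(0); state <- NULL
  sel_first <- NULL
  for (e in 1:5) {
    ep <- mil_train_epoch(m, bags, corpus, k = 2, state = state, lr = 1e-3,
                          seed = derive_seed(99, paste0("e", e)))
    m <- ep$model; state <- ep$state
    losses <- c(losses, ep$train_loss)
    expect_true(all(ep$selected$label == "NC"))
    if (e == 1) sel_first <- ep$selected
  }
  expect_lt(losses[5], losses[1])

  # rerun from scratch: identical selections and losses
  m2 <- nn_init(tile_arch(), "gap", seed = 1)
  ep2 <- mil_train_epoch(m2, bags, corpus, k = 2, state = NULL, lr = 1e-3,
                         seed = derive_seed(99, "e1"))
  expect_identical(ep2$selected, sel_first)
  expect_equal(ep2$train_loss, losses[1])
})

test_that("trained MIL selections land on the lesion", {
  slides <- list()
  for (i in 1:3) {
    for (lab in c("ADC", "SqCC")) {
      id <- paste0(lab, i)
      slides[[id]] <- generate_slide(slide_spec(
        label = lab, lesion_fraction = 0.25, tissue_fraction = 0.7,
        seed = 30 + i + (lab == "SqCC") * 7, width_px = 448, height_px = 448,
        slide_id = id))
    }
    id <- paste0("NC", i)
    slides[[id]] <- generate_slide(slide_spec(
      label = "NC", tissue_fraction = 0.7, seed = 50 + i,
      width_px = 448, height_px = 448, slide_id = id))
  }
  bags <- make_bags(slides)
  fit <- mil_train(nn_init(tile_arch(), "gap", seed = 2), bags, slides,
                   val_bags = bags, k = 1, epochs = 6, lr = 2e-3, seed = 5)
  sel <- fit$selected[fit$selected$label != "NC", ]
  hit <- mapply(function(id, r, cc) {
    les <- slides[[id]]$lesion_mask
    sub <- les[(r * 224 + 1):min((r + 1) * 224, nrow(les)),
               (cc * 224 + 1):min((cc + 1) * 224, ncol(les))]
    mean(sub) > 0.05
  }, sel$slide_id, sel$grid_row, sel$grid_col)
  expect_gte(mean(hit), 0.8)
})
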