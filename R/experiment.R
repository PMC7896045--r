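## Config-driven experiment runner.
##
## Generates (or reuses) a synthetic corpus, trains one or more slide-level
## classification methods on the training split, and evaluates per-class
## one-vs-rest AUCs with DeLong intervals on the test split and on its
## small-lesion subset. Methods sharing a trained tile-level classifier
## (standard MIL, max-feature RF, MIL-RNN) train it once. All randomness is
## derived from the single config seed; the derived seeds are recorded in the
## report, and a rerun with the same config is byte-identical.

VALID_METHODS <- c("MIL_topk", "EM_LR", "EM_SVM", "MaxFeat_RF", "MIL_RNN",
                   "WSI_GAP", "WSI_GMP")

#' Experiment configuration
#'
#' @param methods character vector from `MIL_topk`, `EM_LR`, `EM_SVM`,
#'   `MaxFeat_RF`, `MIL_RNN`, `WSI_GAP`, `WSI_GMP`.
#' @param corpus list of [generate_corpus()] arguments
#'   (`n_per_class`, `size_px`, `small_lesion_quota`, `lesion_fraction_range`).
#' @param fractions train/val/test split fractions.
#' @param k instances per bag; required by the MIL-family methods.
#' @param wsi_channels,tile_channels backbone widths for whole-slide and tile
#'   classifiers.
#' @param wsi_train,mil_train_opts training-loop settings (desk-scale
#'   defaults).
#' @param seed global seed.
#' @param output_dir directory for report.json and learning-curve CSVs;
#'   NULL keeps everything in memory.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(methods,
                              corpus = list(n_per_class = 67L, size_px = 512L,
                                            small_lesion_quota = 0.3,
                                            lesion_fraction_range = c(0.02, 0.35)),
                              fractions = c(0.5, 0.1, 0.4),
                              k = NULL,
                              wsi_channels = c(8L, 16L, 24L, 32L),
                              tile_channels = c(8L, 16L, 32L),
                              wsi_train = list(batch_size = 2L,
                                               steps_per_epoch = 25L,
                                               epochs = 8L, lr = 1e-3),
                              mil_train_opts = list(epochs = 5L, lr = 1e-3,
                                                    batch_size = 8L),
                              seed = 1L, output_dir = NULL) {
  bad <- setdiff(methods, VALID_METHODS)
  if (length(bad) > 0)
    stop("unknown method(s) ", paste(bad, collapse = ", "),
         "; valid methods are: ", paste(VALID_METHODS, collapse = ", "))
  mil_family <- c("MIL_topk", "MaxFeat_RF", "MIL_RNN", "EM_LR", "EM_SVM")
  if (any(methods %in% mil_family) && is.null(k))
    stop("k is required for MIL-family methods (",
         paste(intersect(methods, mil_family), collapse = ", "), ")")
  structure(list(methods = methods, corpus = corpus, fractions = fractions,
                 k = k, wsi_channels = wsi_channels,
                 tile_channels = tile_channels, wsi_train = wsi_train,
                 mil_train_opts = mil_train_opts, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

# Per-class AUC block (test set + small-lesion subset) for one probability
# matrix.
evaluate_probs <- function(probs, labels, small_flags) {
  res <- list()
  for (target in CANCER_LEVELS) {
    cases <- one_vs_rest(probs, labels, target)
    ci <- delong_ci(cases$label, cases$score)
    block <- list(auc = ci$auc, ci_low = ci$ci_low, ci_high = ci$ci_high)
    sl <- small_flags
    if (sum(sl) > 1 && length(unique(cases$label[sl])) == 2) {
      ci_s <- delong_ci(cases$label[sl], cases$score[sl])
      block$small_lesion_auc <- ci_s$auc
      block$small_lesion_ci <- c(ci_s$ci_low, ci_s$ci_high)
    }
    res[[target]] <- block
  }
  res
}

#' Run a configured experiment
#'
#' @param cfg an [experiment_config()].
#' @return (invisibly) a list with `report` (what report.json contains),
#'   `probs` (per-method n_test x 3 matrices), `test_labels`,
#'   `small_flags` (test slides in the small-lesion subset), `curves`, and
#'   `split`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  seeds <- list(corpus = derive_seed(cfg$seed, "corpus"),
                split = derive_seed(cfg$seed, "split"),
                wsi = derive_seed(cfg$seed, "wsi-train"),
                mil = derive_seed(cfg$seed, "mil-train"),
                em = derive_seed(cfg$seed, "em-train"),
                rf = derive_seed(cfg$seed, "rf"),
                rnn = derive_seed(cfg$seed, "rnn"))

  corpus <- do.call(generate_corpus, c(cfg$corpus, list(seed = seeds$corpus)))
  split <- stratified_split(corpus, cfg$fractions, seed = seeds$split)
  test_slides <- corpus[split$test_ids]
  test_labels <- vapply(test_slides, function(s) s$label, character(1))
  small_flags <- vapply(test_slides,
                        function(s) s$label == "NC" || is_small_lesion(s),
                        logical(1))

  probs <- list(); curves <- list(); report_methods <- list()

  need_tile_model <- any(cfg$methods %in% c("MIL_topk", "MaxFeat_RF", "MIL_RNN"))
  tile <- NULL
  if (need_tile_model)
    tile <- fit_mil_components(corpus, split, cfg, seeds)

  for (m in cfg$methods) {
    res <- switch(
      m,
      WSI_GMP = ,
      WSI_GAP = run_wsi_method(m, corpus, split, cfg, seeds, test_slides),
      MIL_topk = list(probs = tile$test_probs_max, curves = tile$curves),
      MaxFeat_RF = run_maxfeat_rf(tile, cfg, seeds),
      MIL_RNN = run_mil_rnn(tile, cfg, seeds),
      EM_LR = ,
      EM_SVM = run_em_method(m, corpus, split, cfg, seeds, test_slides))
    rownames(res$probs) <- NULL
    probs[[m]] <- res$probs
    if (!is.null(res$curves)) curves[[m]] <- res$curves
    report_methods[[m]] <- evaluate_probs(res$probs, test_labels, small_flags)
  }

  report <- list(config = list(methods = cfg$methods, corpus = cfg$corpus,
                               fractions = cfg$fractions, k = cfg$k,
                               seed = cfg$seed),
                 seeds = seeds,
                 n_test = length(test_slides),
                 n_small_lesion_subset = sum(small_flags),
                 results = report_methods)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(cfg$output_dir, "report.json"))
    for (m in names(curves))
      write.csv(curves[[m]],
                file.path(cfg$output_dir, paste0("curves_", m, ".csv")),
                row.names = FALSE)
  }
  invisible(list(report = report, probs = probs, test_labels = test_labels,
                 small_flags = small_flags, curves = curves, split = split,
                 corpus = corpus, tile = tile))
}

run_wsi_method <- function(method, corpus, split, cfg, seeds, test_slides) {
  head <- if (method == "WSI_GMP") "GMP" else "GAP"
  tc <- train_config(batch_size = cfg$wsi_train$batch_size,
                     lr_initial = cfg$wsi_train$lr,
                     lr_decayed = cfg$wsi_train$lr / 10,
                     patience_epochs = max(2L, cfg$wsi_train$epochs %/% 2L),
                     steps_per_epoch = cfg$wsi_train$steps_per_epoch,
                     epochs = cfg$wsi_train$epochs,
                     seed = derive_seed(seeds$wsi, head))
  fit <- train_whole(corpus, split, desk_arch(cfg$wsi_channels), head, tc)
  p <- t(vapply(test_slides, function(s) nn_predict(fit$model, s$image),
                numeric(3)))
  colnames(p) <- CLASS_LEVELS
  list(probs = p, curves = fit$curves, model = fit$model)
}

# Shared tile-level components: trained k-instance MIL classifier plus scored
# test bags (probabilities and embeddings for the aggregation methods).
fit_mil_components <- function(corpus, split, cfg, seeds) {
  bags <- make_bags(corpus)
  tb <- bags[names(bags) %in% split$train_ids]
  vb <- bags[names(bags) %in% split$val_ids]
  sb <- bags[names(bags) %in% split$test_ids]
  model0 <- nn_init(desk_arch(cfg$tile_channels), head = "gap",
                    seed = derive_seed(seeds$mil, "tile-init"))
  fit <- mil_train(model0, tb, corpus, vb, k = cfg$k,
                   epochs = cfg$mil_train_opts$epochs,
                   lr = cfg$mil_train_opts$lr,
                   batch_size = cfg$mil_train_opts$batch_size,
                   seed = seeds$mil)
  score_bags <- function(bgs) lapply(bgs, function(b)
    score_instances(fit$model, b, corpus))
  train_scored <- score_bags(tb)
  test_scored <- score_bags(sb)
  tp <- t(vapply(test_scored, function(s) infer_bag_max(s$probs), numeric(3)))
  colnames(tp) <- CLASS_LEVELS
  list(model = fit$model, curves = fit$curves,
       train_bags = tb, test_bags = sb,
       train_scored = train_scored, test_scored = test_scored,
       train_labels = vapply(tb, function(b) b$label, character(1)),
       test_probs_max = tp)
}

run_maxfeat_rf <- function(tile, cfg, seeds) {
  feat <- function(scored) t(vapply(scored, function(s)
    maxfeat_aggregate(s$embeddings, s$probs, k = cfg$k),
    numeric(ncol(scored[[1]]$embeddings))))
  xtr <- feat(tile$train_scored)
  xte <- feat(tile$test_scored)
  y <- factor(tile$train_labels, levels = CLASS_LEVELS)
  rf <- with_seed(seeds$rf,
                  randomForest::randomForest(x = xtr, y = y, ntree = 300))
  p <- predict(rf, xte, type = "prob")
  p <- p[, CLASS_LEVELS, drop = FALSE]
  list(probs = unname(p) |> `colnames<-`(CLASS_LEVELS), curves = NULL)
}

run_mil_rnn <- function(tile, cfg, seeds) {
  topk_seq <- function(s) {
    cancer <- pmax(s$probs[, 2], s$probs[, 3])
    idx <- select_topk(cancer, k = cfg$k)$indices
    s$embeddings[idx, , drop = FALSE]
  }
  seqs_tr <- lapply(tile$train_scored, topk_seq)
  seqs_te <- lapply(tile$test_scored, topk_seq)
  rnn <- rnn_init(ncol(seqs_tr[[1]]), hidden = 128L, seed = seeds$rnn)
  rnn <- rnn_train(rnn, seqs_tr, match(tile$train_labels, CLASS_LEVELS),
                   epochs = 30L, lr = 5e-3, seed = seeds$rnn)
  p <- t(vapply(seqs_te, function(x) rnn_aggregate(rnn, x), numeric(3)))
  colnames(p) <- CLASS_LEVELS
  list(probs = p, curves = NULL)
}

# EM-CNN: iterated EM selection of representative tiles on blurred
# prediction maps, then a class-histogram bag classifier (LR or RBF-SVM).
run_em_method <- function(method, corpus, split, cfg, seeds, test_slides) {
  bags <- make_bags(corpus)
  tb <- bags[names(bags) %in% split$train_ids]
  sb <- bags[names(bags) %in% split$test_ids]
  model <- nn_init(desk_arch(cfg$tile_channels), head = "gap",
                   seed = derive_seed(seeds$em, "tile-init"))
  state <- NULL
  epochs <- cfg$mil_train_opts$epochs
  for (e in seq_len(epochs)) {
    eseed <- derive_seed(seeds$em, paste0("epoch-", e))
    sel <- NULL
    for (b in tb) {
      n <- nrow(b$coords)
      idx <- if (b$label == "NC") {
        with_seed(derive_seed(eseed, b$slide_id),
                  sample.int(n, min(cfg$k, n)))
      } else {
        sc <- score_instances(model, b, corpus)$probs
        pm <- prediction_map(b, sc)
        es <- em_select(pm, b$label)
        if (length(es$indices) == 0) {
          select_topk(sc, b$label, 1L)$indices
        } else {
          sel_coords <- es$coords
          match(paste(sel_coords[, 1], sel_coords[, 2]),
                paste(b$coords[, 1], b$coords[, 2]))
        }
      }
      sel <- rbind(sel, data.frame(slide_index = b$slide_index,
                                   grid_row = b$coords[idx, 1],
                                   grid_col = b$coords[idx, 2],
                                   label = b$label))
    }
    perm <- with_seed(derive_seed(eseed, "shuffle"), sample.int(nrow(sel)))
    sel <- sel[perm, ]
    if (is.null(state)) state <- adam_init(model)
    for (st in seq(1, nrow(sel), by = cfg$mil_train_opts$batch_size)) {
      rows <- st:min(st + cfg$mil_train_opts$batch_size - 1, nrow(sel))
      images <- lapply(rows, function(r)
        extract_tile(corpus[[sel$slide_index[r]]]$image,
                     sel$grid_row[r], sel$grid_col[r]))
      bg <- nn_batch_grads(model, images, match(sel$label[rows], CLASS_LEVELS))
      upd <- adam_step(model, state, bg$grads, cfg$mil_train_opts$lr)
      model <- upd$model; state <- upd$state
    }
  }
  hists <- function(bgs) t(vapply(bgs, function(b)
    class_histogram(score_instances(model, b, corpus)$probs), numeric(3)))
  htr <- hists(tb)
  hte <- hists(sb)
  clf <- histogram_bag_classifier(htr,
                                  vapply(tb, function(b) b$label, character(1)),
                                  kind = if (method == "EM_LR") "LR" else "SVM",
                                  seed = seeds$em)
  list(probs = predict(clf, hte), curves = NULL)
}
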