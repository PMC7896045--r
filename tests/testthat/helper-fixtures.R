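# Shared fixtures, built in code at test time.

# Small corpus of 448-pixel slides (the minimum two-tile size).
tiny_corpus <- function(n_per_class = 2L, seed = 7L, size_px = 448L,
                        quota = 0.5) {
  generate_corpus(n_per_class, size_px = size_px, seed = seed,
                  small_lesion_quota = quota)
}

# Minimal executable backbones.
tiny_arch <- function() desk_arch(c(4L, 8L))
tile_arch <- function() desk_arch(c(8L, 16L, 32L))

# Lightweight stand-ins for labeled slides when only ids/labels/masks matter.
fake_slide <- function(slide_id, label, lesion_px = 0, tissue_px = 100) {
  tissue <- matrix(FALSE, 10, 10)
  tissue[seq_len(tissue_px)] <- TRUE
  lesion <- matrix(FALSE, 10, 10)
  if (lesion_px > 0) lesion[seq_len(lesion_px)] <- TRUE
  list(slide_id = slide_id, label = label, lesion_mask = lesion,
       tissue_mask = tissue)
}

# Flat colored tiles with pixel noise: three color-coded classes matching the
# synthetic texture model (depth-0 separable).
toy_tile <- function(class_index, seed, side = 32L) {
  base <- list(c(205, 170, 190), c(150, 120, 185), c(185, 135, 110))[[class_index]]
  withr::with_seed(seed, {
    img <- array(0, dim = c(side, side, 3))
    for (ch in 1:3)
      img[, , ch] <- pmin(pmax(base[ch] + rnorm(side * side, sd = 10), 0), 250)
    img
  })
}

# Independent brute-force AUC / DeLong oracles (double loops, no ranks).
oracle_auc <- function(labels, scores) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  s <- 0
  for (a in x) for (b in y) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(x) * length(y))
}

oracle_delong_var <- function(labels, scores) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  v10 <- sapply(seq_len(m), function(i)
    mean((x[i] > y) + 0.5 * (x[i] == y)))
  v01 <- sapply(seq_len(n), function(j)
    mean((x > y[j]) + 0.5 * (x == y[j])))
  var(v10) / m + var(v01) / n
}
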