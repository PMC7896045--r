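## Corpus persistence: one PNG per slide image, one PNG per lesion mask, a
## JSON sidecar with metadata, and a CSV manifest for the corpus.

#' Write a labeled slide to a directory
#'
#' Emits `<id>.png` (image), `<id>_mask.png` (lesion mask, 0/255),
#' `<id>_tissue.png` (tissue mask) and `<id>.json` (metadata sidecar).
#'
#' @param slide a `labeled_slide`.
#' @param dir output directory (created if needed).
#' @return the sidecar path, invisibly.
#' @export
write_slide <- function(slide, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- slide$slide_id
  write_image(slide$image, file.path(dir, paste0(id, ".png")))
  png::writePNG(slide$lesion_mask * 1, file.path(dir, paste0(id, "_mask.png")))
  png::writePNG(slide$tissue_mask * 1, file.path(dir, paste0(id, "_tissue.png")))
  meta <- list(slide_id = id, label = slide$label,
               um_per_px = slide$um_per_px,
               lesion_fraction = slide$lesion_fraction)
  path <- file.path(dir, paste0(id, ".json"))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a labeled slide written by [write_slide()]
#' @param dir directory.
#' @param slide_id slide identifier.
#' @return a `labeled_slide`.
#' @export
read_slide <- function(dir, slide_id) {
  meta <- jsonlite::fromJSON(file.path(dir, paste0(slide_id, ".json")))
  img <- read_image(file.path(dir, paste0(slide_id, ".png")))
  lesion <- png::readPNG(file.path(dir, paste0(slide_id, "_mask.png"))) > 0.5
  tissue <- png::readPNG(file.path(dir, paste0(slide_id, "_tissue.png"))) > 0.5
  structure(list(image = img, label = meta$label, lesion_mask = lesion,
                 tissue_mask = tissue, um_per_px = meta$um_per_px,
                 slide_id = meta$slide_id,
                 lesion_fraction = meta$lesion_fraction),
            class = "labeled_slide")
}

#' Corpus manifest
#'
#' @param slides list of `labeled_slide` objects.
#' @param split optional [stratified_split()] result; adds a `split` column.
#' @return data.frame (slide_id, label, lesion_fraction[, split]).
#' @export
corpus_manifest <- function(slides, split = NULL) {
  df <- data.frame(
    slide_id = vapply(slides, function(s) s$slide_id, character(1)),
    label = vapply(slides, function(s) s$label, character(1)),
    lesion_fraction = vapply(slides, function(s) s$lesion_fraction, numeric(1)),
    row.names = NULL)
  if (!is.null(split)) {
    df$split <- NA_character_
    df$split[df$slide_id %in% split$train_ids] <- "train"
    df$split[df$slide_id %in% split$val_ids] <- "val"
    df$split[df$slide_id %in% split$test_ids] <- "test"
  }
  df
}
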