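# End-to-end convenience: per-image color models -> grid features -> tissue
# clusters trained on one marked image -> classification and epithelium
# estimates for every image.

#' Run the full epithelium-estimation pipeline on a set of micrographs
#'
#' For each micrograph a four-color stain model is fitted to its own pixels
#' (stain intensity varies slide to slide, and per-image fitting absorbs
#' that), the image is tiled into grid cells and featurized. One image —
#' `training_index` — must carry an epithelium annotation mask: its cells are
#' marked, training labels derived (lumen rule included) and the
#' epithelial/stromal/luminal cluster model trained there. All images are then
#' classified with that model and per-image epithelium estimates computed.
#'
#' @param micrographs List of `synthetic_micrograph` objects, or of lists with
#'   an `image` element (0--255 RGB array).
#' @param training_index Which micrograph carries the annotation.
#' @param training_mask Logical epithelium mask for the training image;
#'   defaults to the synthetic ground truth ([truth_epithelium_mask()]) when
#'   available.
#' @param axes Three semantic ratio names spanning the classification space.
#' @param cell_size Grid cell edge in pixels.
#' @param seed Integer seed; image `i` is fitted with seed `seed + i`.
#' @param n_init Color-model restarts per image.
#' @param white_lumen_threshold Lumen rule cutoff.
#' @param mark_threshold Cell-coverage threshold for the annotation mask.
#' @param centroids_only Passed to [train_class_model()].
#' @return A list with `estimates` (one [estimate_image()] row per image,
#'   plus `truth_percent` where ground truth is available), `class_model`,
#'   `color_models`, `tables` and `labels` (per-image classification factors).
#' @export
epithelium_pipeline <- function(micrographs, training_index = 1L,
                                training_mask = NULL,
                                axes = c("white", "dark_pink", "purple"),
                                cell_size = 20L, seed = 1L, n_init = 10L,
                                white_lumen_threshold = 0.7,
                                mark_threshold = 0.5,
                                centroids_only = TRUE) {
  stopifnot(length(micrographs) >= 1L,
            training_index >= 1L, training_index <= length(micrographs))

  color_models <- vector("list", length(micrographs))
  tables <- vector("list", length(micrographs))
  for (i in seq_along(micrographs)) {
    img <- micrographs[[i]]$image
    color_models[[i]] <- fit_color_model(img, seed = seed + i, n_init = n_init)
    labmap <- assign_color_labels(img, color_models[[i]])
    tables[[i]] <- tile_and_featurize(labmap, cell_size = cell_size)
  }

  if (is.null(training_mask)) {
    tm <- micrographs[[training_index]]
    if (!inherits(tm, "synthetic_micrograph")) {
      stop("supply `training_mask` for non-synthetic training images",
           call. = FALSE)
    }
    training_mask <- truth_epithelium_mask(tm)
  }
  train_tab <- mark_epithelial_cells(tables[[training_index]], training_mask,
                                     cell_fraction_threshold = mark_threshold)
  class_model <- train_class_model(train_tab, axes = axes, seed = seed,
                                   white_lumen_threshold = white_lumen_threshold,
                                   centroids_only = centroids_only)

  labels <- lapply(tables, classify_cells, model = class_model)
  est <- do.call(rbind, lapply(seq_along(labels), function(i) {
    estimate_image(labels[[i]], image_id = sprintf("image_%02d", i))
  }))
  est$truth_percent <- vapply(micrographs, function(m) {
    if (inherits(m, "synthetic_micrograph")) {
      truth_epithelium_percentage(m)
    } else {
      NA_real_
    }
  }, numeric(1L))

  list(estimates = est, class_model = class_model,
       color_models = color_models, tables = tables, labels = labels)
}
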