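# Tissue classification of grid cells in color-ratio space: derive training
# labels from the manual marks plus the white-content lumen rule, build the
# three tissue clusters with k-means, classify by nearest cluster, and
# cross-validate on held-out cells.

.tissue_classes <- c("epithelial", "stromal", "luminal")

#' Derive per-cell tissue training labels
#'
#' Applies the lumen rule first: any cell whose white-color ratio is strictly
#' greater than `white_lumen_threshold` (default 0.7) is luminal regardless of
#' the manual mark. Remaining cells are epithelial if marked, stromal
#' otherwise. Excluded cells get `NA`.
#'
#' @param table A marked `grid_cell_table` (see [mark_epithelial_cells()]).
#' @param white_lumen_threshold White-ratio cutoff above which a cell is
#'   luminal (strict inequality).
#' @return `table` with a `tissue_class` factor column
#'   (levels epithelial, stromal, luminal).
#' @export
derive_training_labels <- function(table, white_lumen_threshold = 0.7) {
  stopifnot(white_lumen_threshold > 0, white_lumen_threshold < 1)
  if (!"white" %in% names(table)) {
    stop("`table` lacks a white ratio column", call. = FALSE)
  }
  active <- !table$excluded
  if (any(active & is.na(table$epithelial_marked))) {
    stop("epithelial marks missing: run mark_epithelial_cells() first",
         call. = FALSE)
  }
  cls <- ifelse(table$white > white_lumen_threshold, "luminal",
                ifelse(table$epithelial_marked, "epithelial", "stromal"))
  cls[!active] <- NA
  table$tissue_class <- factor(cls, levels = .tissue_classes)
  table
}

#' Train the epithelial/stromal/luminal cluster model
#'
#' Places the three tissue centroids at the class-conditional mean vectors of
#' the cells' chosen color ratios (the default, `centroids_only = TRUE`).
#' With `centroids_only = FALSE` the centroids are instead refined by
#' unsupervised k-means (k = 3) initialized at those class means, each final
#' centroid inheriting the label of the class that seeded it; because the
#' refinement ignores the known labels it can drift when classes touch
#' (mixed boundary cells), so a warning is recorded when the majority true
#' class among a centroid's members disagrees with its label.
#'
#' @param table A `grid_cell_table` with a `tissue_class` column (or with
#'   marks, in which case labels are derived with `white_lumen_threshold`).
#' @param axes Three semantic ratio names spanning the classification space.
#' @param seed Integer seed recorded in the model (training itself is
#'   deterministic given the initialization).
#' @param white_lumen_threshold Lumen rule cutoff, stored with the model and
#'   used if labels must be derived.
#' @param centroids_only If `TRUE` (default), use class-conditional means
#'   directly; if `FALSE`, refine them by unsupervised k-means.
#' @param max_iter,tol Lloyd's iteration cap and convergence tolerance.
#' @return An object of class `tissue_class_model`: `centroids` (3 x 3 matrix,
#'   rows epithelial/stromal/luminal), `axes`, `white_lumen_threshold`,
#'   `seed` and `training_meta`.
#' @export
train_class_model <- function(table, axes = c("white", "dark_pink", "purple"),
                              seed = 1L, white_lumen_threshold = 0.7,
                              centroids_only = TRUE,
                              max_iter = 300L, tol = 1e-6) {
  if (is.null(table$tissue_class)) {
    table <- derive_training_labels(table, white_lumen_threshold)
  }
  keep <- !is.na(table$tissue_class)
  feats <- select_ratio_axes(table, axes)[keep, , drop = FALSE]
  cls <- table$tissue_class[keep]
  counts <- tabulate(cls, 3L)
  if (any(counts == 0L)) {
    stop(sprintf("empty training class: %s",
                 paste(.tissue_classes[counts == 0L], collapse = ", ")),
         call. = FALSE)
  }
  init <- t(vapply(.tissue_classes,
                   function(g) colMeans(feats[cls == g, , drop = FALSE]),
                   numeric(3L)))
  if (centroids_only) {
    centroids <- init
    iters <- 0L
  } else {
    fit <- .lloyd(feats, init, max_iter = max_iter, tol = tol)
    centroids <- fit$centers
    iters <- fit$iterations
    member_cls <- fit$labels
    for (j in 1:3) {
      members <- cls[member_cls == j]
      if (length(members) &&
          which.max(tabulate(members, 3L)) != j) {
        warning(sprintf(paste0("centroid '%s' is dominated by cells of another",
                               " class; the tissue clusters may have drifted"),
                        .tissue_classes[j]), call. = FALSE)
      }
    }
  }
  dimnames(centroids) <- list(.tissue_classes, axes)
  structure(list(centroids = centroids, axes = axes,
                 white_lumen_threshold = white_lumen_threshold,
                 seed = as.integer(seed), iterations = iters,
                 training_meta = list(n_cells = nrow(feats),
                                      class_counts = as.integer(counts))),
            class = "tissue_class_model")
}

#' Classify grid cells by nearest tissue cluster
#'
#' Each non-excluded cell is assigned the label of the centroid minimizing
#' squared Euclidean distance in the model's ratio space; exact ties are
#' broken in the order epithelial < stromal < luminal. Excluded cells receive
#' `NA`.
#'
#' @param table A `grid_cell_table` featurized with the same semantic colors
#'   as the model's axes.
#' @param model A [train_class_model()] result.
#' @return A factor of length `nrow(table)` with levels
#'   epithelial, stromal, luminal.
#' @export
classify_cells <- function(table, model) {
  stopifnot(inherits(model, "tissue_class_model"))
  if (!all(model$axes %in% names(table))) {
    stop(sprintf("axis mismatch: table lacks ratio column(s) %s",
                 paste(setdiff(model$axes, names(table)), collapse = ", ")),
         call. = FALSE)
  }
  feats <- select_ratio_axes(table, model$axes)
  lab <- .tissue_classes[.nearest_centroid(feats, model$centroids)]
  if (!is.null(table$excluded)) lab[table$excluded] <- NA
  factor(lab, levels = .tissue_classes)
}

#' Cross-validate the grid-cell classifier on marked images
#'
#' For each marked image, a seeded uniform split assigns `split_fraction` of
#' the non-excluded cells to training; a tissue-cluster model is trained on
#' that half and the held-out half is classified. Evaluation is binary —
#' epithelial versus non-epithelial (stromal and luminal pooled) — and all
#' three rates share the same denominator (every evaluated cell), so per image
#' accuracy + false-positive rate + false-negative rate = 100 exactly.
#' `area_r2` is the squared Pearson correlation between predicted and marked
#' epithelial cell counts per image across images (cell counts are
#' proportional to areas at fixed cell size).
#'
#' @param tables A list of marked `grid_cell_table`s (one per image).
#' @param axes Three semantic ratio names.
#' @param split_fraction Fraction of cells used for training (default 0.5).
#' @param seed Integer seed for the splits (recorded in the report).
#' @param white_lumen_threshold Lumen rule cutoff.
#' @param centroids_only Passed to [train_class_model()].
#' @return An object of class `validation_report`: `per_image` data frame
#'   (accuracy, false-positive and false-negative percentages, predicted and
#'   marked epithelial cell counts), across-image means and standard
#'   deviations, `area_r2`, `split_fraction` and `seed`.
#' @export
cross_validate <- function(tables, axes = c("white", "dark_pink", "purple"),
                           split_fraction = 0.5, seed = 1L,
                           white_lumen_threshold = 0.7,
                           centroids_only = TRUE) {
  stopifnot(length(tables) >= 1L, split_fraction > 0, split_fraction < 1)
  labeled <- lapply(tables, derive_training_labels,
                    white_lumen_threshold = white_lumen_threshold)
  splits <- .with_seed(seed, lapply(labeled, function(tab) {
    idx <- which(!tab$excluded)
    if (!length(idx)) stop("an image has zero evaluable cells", call. = FALSE)
    sample(idx, round(split_fraction * length(idx)))
  }))

  rows <- lapply(seq_along(labeled), function(i) {
    tab <- labeled[[i]]
    train_idx <- splits[[i]]
    val_idx <- setdiff(which(!tab$excluded), train_idx)
    if (!length(val_idx)) stop("an image has an empty validation half",
                               call. = FALSE)
    model <- train_class_model(tab[train_idx, , drop = FALSE], axes = axes,
                               seed = seed,
                               white_lumen_threshold = white_lumen_threshold,
                               centroids_only = centroids_only)
    val <- tab[val_idx, , drop = FALSE]
    pred_epi <- classify_cells(val, model) == "epithelial"
    truth_epi <- val$tissue_class == "epithelial"
    n <- length(val_idx)
    data.frame(image = i,
               n_cells = n,
               accuracy = 100 * sum(pred_epi == truth_epi) / n,
               false_positive = 100 * sum(pred_epi & !truth_epi) / n,
               false_negative = 100 * sum(!pred_epi & truth_epi) / n,
               predicted_epithelial_cells = sum(pred_epi),
               marked_epithelial_cells = sum(truth_epi))
  })
  per_image <- do.call(rbind, rows)

  area_r2 <- NA_real_
  if (nrow(per_image) >= 2L &&
      stats::sd(per_image$predicted_epithelial_cells) > 0 &&
      stats::sd(per_image$marked_epithelial_cells) > 0) {
    area_r2 <- stats::cor(per_image$predicted_epithelial_cells,
                          per_image$marked_epithelial_cells)^2
  }

  structure(list(per_image = per_image,
                 accuracy_mean = mean(per_image$accuracy),
                 accuracy_sd = stats::sd(per_image$accuracy),
                 false_positive_mean = mean(per_image$false_positive),
                 false_positive_sd = stats::sd(per_image$false_positive),
                 false_negative_mean = mean(per_image$false_negative),
                 false_negative_sd = stats::sd(per_image$false_negative),
                 area_r2 = area_r2,
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("cross-validation over %d image(s), %.0f%%/%.0f%% split (seed %d)\n",
              nrow(x$per_image), 100 * x$split_fraction,
              100 * (1 - x$split_fraction), x$seed))
  cat(sprintf("  accuracy        %6.2f +/- %.2f %%\n",
              x$accuracy_mean, x$accuracy_sd))
  cat(sprintf("  false positives %6.2f +/- %.2f %%\n",
              x$false_positive_mean, x$false_positive_sd))
  cat(sprintf("  false negatives %6.2f +/- %.2f %%\n",
              x$false_negative_mean, x$false_negative_sd))
  if (!is.na(x$area_r2)) {
    cat(sprintf("  epithelial-area R^2 across images: %.3f\n", x$area_r2))
  }
  invisible(x)
}

#' Write / read a tissue class model as a plain-text YAML file
#'
#' @param model A `tissue_class_model`.
#' @param path File path.
#' @return `write_class_model` returns `path` invisibly; `read_class_model`
#'   returns the restored model.
#' @export
write_class_model <- function(model, path) {
  stopifnot(inherits(model, "tissue_class_model"))
  yaml::write_yaml(list(centroids = unname(apply(model$centroids, 1L, c,
                                                 simplify = FALSE)),
                        classes = rownames(model$centroids),
                        axes = model$axes,
                        white_lumen_threshold = model$white_lumen_threshold,
                        seed = model$seed),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname write_class_model
#' @export
read_class_model <- function(path) {
  y <- yaml::read_yaml(path)
  centroids <- do.call(rbind, y$centroids)
  dimnames(centroids) <- list(y$classes, y$axes)
  structure(list(centroids = centroids, axes = y$axes,
                 white_lumen_threshold = y$white_lumen_threshold,
                 seed = y$seed, iterations = NA_integer_,
                 training_meta = NULL),
            class = "tissue_class_model")
}
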