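# Pixel-level color segmentation: k-means on raw RGB into the four dominant
# H&E colors (white, light pink, dark pink, purple).

.semantic_colors <- c("white", "light_pink", "dark_pink", "purple")

# Order fitted centroids against a reference palette by the permutation
# minimizing total squared distance (k is small, enumerate).
.match_palette_order <- function(centroids, reference) {
  k <- nrow(centroids)
  perms <- .permutations(k)
  d2 <- .pairwise_sqdist(centroids, reference)
  costs <- apply(perms, 1L, function(p) sum(d2[cbind(seq_len(k), p)]))
  perms[which.min(costs), ]
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  unname(out)
}

#' Fit a four-color stain model to an H&E micrograph
#'
#' Clusters pixel RGB values with k-means (Lloyd's algorithm, careful
#' k-means++-style seeding, best of `n_init` restarts by within-cluster sum of
#' squares). Centroids are reported on the unit RGB scale and given semantic
#' names: by default the four centroids are sorted by luminance, brightest to
#' darkest, as white, light pink, dark pink and purple — the brightness
#' ordering of lumen, stroma and nuclei in an H&E stain. Supplying
#' `reference_palette` instead names each centroid after its nearest reference
#' color.
#'
#' @param image RGB array (h x w x 3), on the 0--255 or 0--1 scale.
#' @param k Number of color clusters (default 4; semantic names require 4).
#' @param seed Integer seed controlling initialization (and the fitting
#'   subsample, if any).
#' @param n_init Number of random restarts; the fit with the lowest inertia is
#'   kept.
#' @param exclusion_mask Optional logical matrix matching the image; `TRUE`
#'   pixels (e.g. trimmed or micro-dissected regions) are excluded from the
#'   fit.
#' @param reference_palette Optional k x 3 RGB matrix (0--255 or 0--1 scale)
#'   whose row names label the centroids via nearest-color matching.
#' @param max_fit_pixels Images with more pixels than this are fit on a seeded
#'   uniform subsample of this size (the model is then applied to all pixels).
#' @param max_iter,tol Lloyd's iteration cap and centroid-movement convergence
#'   tolerance (RGB units on the unit scale).
#' @return An object of class `color_model`: centroids (k x 3, unit scale,
#'   rows named by `semantic_order`), `semantic_order`, `seed`, `inertia`
#'   (final within-cluster sum of squares on the fitting set) and
#'   `iterations`.
#' @export
#' @examples
#' m <- generate_micrograph(synthetic_spec(width_px = 80, height_px = 80,
#'                                         color_noise_sd = 0, seed = 2))
#' fit_color_model(m$image, seed = 1, n_init = 2)
fit_color_model <- function(image, k = 4L, seed = 1L, n_init = 10L,
                            exclusion_mask = NULL, reference_palette = NULL,
                            max_fit_pixels = 1e6, max_iter = 300L, tol = 1e-6) {
  stopifnot(k >= 1L, n_init >= 1L)
  img <- .image_to_unit(image)
  x <- .pixel_matrix(img)
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(img)[1:2])) {
      stop("`exclusion_mask` dimensions must match the image", call. = FALSE)
    }
    x <- x[!as.vector(exclusion_mask), , drop = FALSE]
  }
  # distinct-color count via an injective-for-8-bit-data numeric key
  key <- drop(x %*% c(1, 2^10, 2^20))
  n_distinct <- length(unique(key))
  if (n_distinct < k) {
    stop(sprintf("degenerate input: only %d distinct pixel color(s), need >= %d",
                 n_distinct, k), call. = FALSE)
  }

  fit <- .with_seed(seed, {
    xfit <- if (nrow(x) > max_fit_pixels) {
      x[sample.int(nrow(x), max_fit_pixels), , drop = FALSE]
    } else {
      x
    }
    .kmeans_restarts(xfit, k, n_init = n_init, max_iter = max_iter, tol = tol)
  })

  centroids <- fit$centers
  if (!is.null(reference_palette)) {
    ref <- as.matrix(reference_palette)
    if (nrow(ref) != k) stop("`reference_palette` must have k rows", call. = FALSE)
    if (max(ref) > 1) ref <- ref / 255
    ord <- order(.match_palette_order(centroids, ref))
    nm <- rownames(reference_palette)
    if (is.null(nm)) nm <- if (k == 4L) .semantic_colors else paste0("color_", 1:k)
  } else {
    ord <- order(.luminance(centroids), decreasing = TRUE)
    nm <- if (k == 4L) .semantic_colors else paste0("color_", 1:k)
  }
  centroids <- centroids[ord, , drop = FALSE]
  dimnames(centroids) <- list(nm, c("r", "g", "b"))

  structure(list(centroids = centroids, semantic_order = nm,
                 seed = as.integer(seed), n_init = as.integer(n_init),
                 inertia = fit$inertia, iterations = fit$iterations,
                 inertia_trace = fit$inertia_trace),
            class = "color_model")
}

#' Assign every pixel to its nearest stain-color centroid
#'
#' Each pixel is mapped to the color-model centroid minimizing squared
#' Euclidean RGB distance; exact ties go to the lowest centroid index (the
#' brightest color under the default semantic ordering).
#'
#' @param image RGB array (h x w x 3), 0--255 or 0--1 scale.
#' @param model A [fit_color_model()] result.
#' @return An object of class `color_label_map`: `labels` (integer matrix,
#'   values `1..k` indexing `model$semantic_order`) and `model`.
#' @export
assign_color_labels <- function(image, model) {
  stopifnot(inherits(model, "color_model"))
  img <- .image_to_unit(image)
  d <- dim(img)
  lab <- .nearest_centroid(.pixel_matrix(img), model$centroids)
  structure(list(labels = matrix(lab, d[1L], d[2L]), model = model),
            class = "color_label_map")
}

#' @export
print.color_model <- function(x, ...) {
  cat(sprintf("H&E color model: %d centroids (seed %d, %d restart(s), inertia %.4g)\n",
              nrow(x$centroids), x$seed, x$n_init, x$inertia))
  print(round(x$centroids, 4))
  invisible(x)
}

#' Write / read a color model as a plain-text YAML file
#'
#' @param model A `color_model`.
#' @param path File path.
#' @return `write_color_model` returns `path` invisibly; `read_color_model`
#'   returns the restored `color_model`.
#' @export
write_color_model <- function(model, path) {
  stopifnot(inherits(model, "color_model"))
  yaml::write_yaml(list(centroids = unname(apply(model$centroids, 1L, c,
                                                 simplify = FALSE)),
                        semantic_order = model$semantic_order,
                        seed = model$seed, inertia = model$inertia),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname write_color_model
#' @export
read_color_model <- function(path) {
  y <- yaml::read_yaml(path)
  centroids <- do.call(rbind, y$centroids)
  dimnames(centroids) <- list(y$semantic_order, c("r", "g", "b"))
  structure(list(centroids = centroids, semantic_order = y$semantic_order,
                 seed = y$seed, n_init = NA_integer_, inertia = y$inertia,
                 iterations = NA_integer_, inertia_trace = NULL),
            class = "color_model")
}
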