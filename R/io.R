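# Raster and spec I/O. Images travel as PNG (TIFF read/write available when
# the tiff package is installed); truth labels as a single-channel PNG with
# codes 0 = lumen, 1 = stroma, 2 = epithelium.

#' Read an RGB image from PNG or TIFF
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return An h x w x 3 array on the 0--255 scale. Grayscale input is
#'   replicated across channels; an alpha channel is dropped.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the `tiff` package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE))
  if (length(dim(raw)) == 2L) raw <- array(raw, c(dim(raw), 1L))
  if (dim(raw)[3L] == 1L) raw <- raw[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(raw)[3L] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  round(raw * 255)
}

#' Write an RGB image to PNG or TIFF
#'
#' @param image RGB array, 0--255 or 0--1 scale.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- .image_to_unit(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("writing TIFF requires the `tiff` package", call. = FALSE)
      }
      tiff::writeTIFF(img, path)
    },
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE))
  invisible(path)
}

#' Write / read a synthetic micrograph (image + truth labels)
#'
#' The image is written as RGB PNG and the truth labels as a single-channel
#' PNG with pixel codes 0 = lumen, 1 = stroma, 2 = epithelium (stored as
#' intensities 0, 1, 2 out of 255).
#'
#' @param m A `synthetic_micrograph`.
#' @param image_path Output PNG path for the image.
#' @param labels_path Optional output PNG path for the truth labels.
#' @return `write_micrograph` returns `image_path` invisibly;
#'   `read_micrograph` returns a list with `image` (0--255 array) and `truth`
#'   (integer matrix or `NULL`).
#' @export
write_micrograph <- function(m, image_path, labels_path = NULL) {
  stopifnot(inherits(m, "synthetic_micrograph"))
  png::writePNG(m$image / 255, image_path)
  if (!is.null(labels_path)) {
    png::writePNG(m$truth / 255, labels_path)
  }
  invisible(image_path)
}

#' @rdname write_micrograph
#' @export
read_micrograph <- function(image_path, labels_path = NULL) {
  image <- read_image(image_path)
  truth <- NULL
  if (!is.null(labels_path)) {
    truth <- round(png::readPNG(labels_path) * 255)
    storage.mode(truth) <- "integer"
    if (!all(truth %in% 0:2)) {
      stop("label raster must use codes {0, 1, 2}", call. = FALSE)
    }
  }
  list(image = image, truth = truth)
}

#' Write / read a synthetic-micrograph spec as a plain-text YAML file
#'
#' @param spec A [synthetic_spec()].
#' @param path File path.
#' @return `write_synthetic_spec` returns `path` invisibly;
#'   `read_synthetic_spec` returns the restored `synthetic_spec`.
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  y <- unclass(spec)
  y$palette <- unname(apply(spec$palette, 1L, c, simplify = FALSE))
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  y$palette <- do.call(rbind, y$palette)
  do.call(synthetic_spec, y)
}
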