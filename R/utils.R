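# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Rec. 601 luma; used to order stain centroids from lumen (bright) to nuclei (dark).
.luminance <- function(rgb) {
  rgb <- matrix(rgb, ncol = 3L)
  drop(rgb %*% c(0.299, 0.587, 0.114))
}

.check_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L) {
    stop(sprintf("`%s` must be an h x w x 3 RGB array", arg), call. = FALSE)
  }
  if (anyNA(image) || min(image) < 0) {
    stop(sprintf("`%s` must contain finite non-negative intensities", arg),
         call. = FALSE)
  }
  invisible(image)
}

# Accept images on either the 8-bit (0..255) or unit (0..1) scale; return unit scale.
.image_to_unit <- function(image) {
  .check_image(image)
  if (max(image) > 1) image / 255 else image
}

# Flatten an h x w x 3 array into an n x 3 pixel matrix (column-major pixel order).
.pixel_matrix <- function(image) {
  d <- dim(image)
  matrix(image, nrow = d[1L] * d[2L], ncol = 3L,
         dimnames = list(NULL, c("r", "g", "b")))
}

# Squared Euclidean distances between rows of x (n x d) and centers (k x d).
.pairwise_sqdist <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0 # numerical guard
  d2
}

# Nearest-centroid labels with ties broken toward the lowest centroid index.
.nearest_centroid <- function(x, centers) {
  max.col(-.pairwise_sqdist(x, centers), ties.method = "first")
}
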