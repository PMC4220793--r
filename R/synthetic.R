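# Synthetic H&E-like micrographs with per-pixel ground truth.
#
# Glands are drawn as randomly placed annuli: a purple epithelial ring around
# a white lumen core, on a stromal background mixed from two pink tones. The
# geometry mimics the ring-of-epithelium-around-lumen architecture of benign
# and malignant prostate glands at low magnification.

#' Default H&E palette used by the synthetic generator
#'
#' Four RGB triplets on the 0--255 scale, ordered white, light pink, dark
#' pink, purple. Luminance is strictly decreasing in that order, matching the
#' brightness ordering of lumen, stroma and nuclei in an H&E stain.
#'
#' @return A 4 x 3 numeric matrix with row names
#'   `white`, `light_pink`, `dark_pink`, `purple`.
#' @export
#' @examples
#' he_palette()
he_palette <- function() {
  matrix(c(245, 242, 245,
           238, 180, 200,
           205, 112, 140,
           120, 60, 140),
         nrow = 4L, ncol = 3L, byrow = TRUE,
         dimnames = list(c("white", "light_pink", "dark_pink", "purple"),
                         c("r", "g", "b")))
}

#' Specification of a synthetic H&E micrograph
#'
#' Bundles the parameters of the synthetic-micrograph generator and validates
#' them. `target_epithelium_fraction` is the epithelium share of the *tissue*
#' (epithelium / (epithelium + stroma)); `lumen_fraction` is the lumen share
#' of the whole image. At the default 2 microns per pixel a 20 x 20 pixel
#' grid cell covers 0.04 x 0.04 mm^2 of tissue.
#'
#' @param width_px,height_px Image dimensions in pixels.
#' @param microns_per_pixel Physical pixel size in microns (default 2).
#' @param target_epithelium_fraction Desired epithelium / (epithelium + stroma)
#'   fraction, in `[0, 1]`.
#' @param lumen_fraction Desired lumen fraction of the whole image, in `[0, 1]`.
#'   Together with the epithelium target it must not exceed 1.
#' @param palette 4 x 3 matrix of RGB triplets on the 0--255 scale for white,
#'   light pink, dark pink and purple (in that row order); entries must be
#'   pairwise distinct and the white entry must have the highest luminance.
#' @param color_noise_sd Per-channel Gaussian noise standard deviation on the
#'   0--255 scale (0 disables noise).
#' @param gland_count Nominal number of glands used to size the annuli; the
#'   generator keeps placing glands until the epithelium target is reached.
#' @param seed Integer seed; generation is bit-reproducible for a fixed spec.
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' synthetic_spec(target_epithelium_fraction = 0.3, seed = 11)
synthetic_spec <- function(width_px = 320L, height_px = 320L,
                           microns_per_pixel = 2,
                           target_epithelium_fraction = 0.4,
                           lumen_fraction = 0.1,
                           palette = he_palette(),
                           color_noise_sd = 8,
                           gland_count = 16L,
                           seed = 1L) {
  stopifnot(width_px >= 1, height_px >= 1, microns_per_pixel > 0,
            color_noise_sd >= 0, gland_count >= 0)
  if (target_epithelium_fraction < 0 || target_epithelium_fraction > 1) {
    stop("`target_epithelium_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (lumen_fraction < 0 || lumen_fraction > 1) {
    stop("`lumen_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (target_epithelium_fraction + lumen_fraction > 1) {
    stop("`target_epithelium_fraction` + `lumen_fraction` must not exceed 1",
         call. = FALSE)
  }
  palette <- as.matrix(palette)
  if (!all(dim(palette) == c(4L, 3L)) || min(palette) < 0 || max(palette) > 255) {
    stop("`palette` must be a 4 x 3 RGB matrix on the 0-255 scale", call. = FALSE)
  }
  if (anyDuplicated(palette)) {
    stop("`palette` entries must be pairwise distinct", call. = FALSE)
  }
  lum <- .luminance(palette)
  if (which.max(lum) != 1L) {
    stop("the first (white) palette entry must have the highest luminance",
         call. = FALSE)
  }
  rownames(palette) <- c("white", "light_pink", "dark_pink", "purple")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 microns_per_pixel = microns_per_pixel,
                 target_epithelium_fraction = target_epithelium_fraction,
                 lumen_fraction = lumen_fraction,
                 palette = palette,
                 color_noise_sd = color_noise_sd,
                 gland_count = as.integer(gland_count),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Paint one gland (epithelial annulus + lumen core) into the truth raster.
.paint_annulus <- function(truth, cy, cx, r_out, r_in) {
  h <- nrow(truth); w <- ncol(truth)
  r0 <- max(1L, floor(cy - r_out)); r1 <- min(h, ceiling(cy + r_out))
  c0 <- max(1L, floor(cx - r_out)); c1 <- min(w, ceiling(cx + r_out))
  d2 <- outer((r0:r1 - cy)^2, (c0:c1 - cx)^2, "+")
  block <- truth[r0:r1, c0:c1, drop = FALSE]
  block[d2 <= r_out^2] <- 2L
  if (r_in > 0) block[d2 <= r_in^2] <- 0L
  truth[r0:r1, c0:c1] <- block
  truth
}

#' Generate a synthetic H&E micrograph with known tissue labels
#'
#' Draws gland-like annuli (purple epithelial ring, white lumen core) on a
#' pink stromal background, then adds independent per-channel Gaussian color
#' noise clipped to `[0, 255]`. Glands are placed at seeded random positions
#' until the realized epithelium fraction (epithelium / (epithelium + stroma))
#' reaches the target; the generator guarantees the realized fraction is
#' within 0.05 of the target or signals an error.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_micrograph`: a list with `image`
#'   (h x w x 3 array, 0--255), `truth` (h x w integer matrix with codes
#'   0 = lumen, 1 = stroma, 2 = epithelium) and `spec`.
#' @export
#' @examples
#' m <- generate_micrograph(synthetic_spec(width_px = 120, height_px = 120,
#'                                         seed = 3))
#' truth_epithelium_percentage(m)
generate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$height_px; w <- spec$width_px
  n_px <- h * w
  ef <- spec$target_epithelium_fraction
  lf <- spec$lumen_fraction
  if (ef > 0 && spec$gland_count < 1L) {
    stop("invalid spec: a positive epithelium target requires gland_count >= 1",
         call. = FALSE)
  }

  out <- .with_seed(spec$seed, {
    truth <- matrix(1L, h, w)
    # stromal tone field: coarse blocks of the two pink palette rows
    bs <- 16L
    br <- (h - 1L) %/% bs + 1L
    bc <- (w - 1L) %/% bs + 1L
    tone_block <- matrix(sample(c(2L, 3L), br * bc, replace = TRUE,
                                prob = c(0.55, 0.45)), br, bc)
    tone <- tone_block[(seq_len(h) - 1L) %/% bs + 1L,
                       (seq_len(w) - 1L) %/% bs + 1L, drop = FALSE]

    if (ef > 0) {
      # lumen-to-epithelium area ratio per gland chosen so that the whole-image
      # lumen fraction tracks its target as glands accumulate
      rho <- if (lf > 0) lf / (ef * (1 - lf)) else 0
      core_share <- rho / (1 + rho) # r_in^2 / r_out^2
      epi_target_px <- ef * (1 - lf) * n_px
      # cap the per-gland ring so one gland moves the realized fraction < ~3%
      ring_area <- min(epi_target_px / spec$gland_count,
                       0.03 * n_px * (1 - lf))
      r_out <- max(sqrt(ring_area / (pi * (1 - core_share))), 6)
      r_in <- sqrt(core_share) * r_out
      if (2 * r_out + 4 > min(h, w)) {
        stop("infeasible geometry: glands do not fit in the image; ",
             "increase the image size or gland_count", call. = FALSE)
      }
      max_glands <- max(spec$gland_count * 12L, 24L)
      epi_frac <- 0
      centers <- matrix(0, max_glands, 2L)
      for (g in seq_len(max_glands)) {
        # centers anywhere in the frame; annuli are clipped at the borders,
        # as glands cut by the tile edge are in real micrographs
        cy <- stats::runif(1, 1, h)
        cx <- stats::runif(1, 1, w)
        centers[g, ] <- c(cy, cx)
        truth <- .paint_annulus(truth, cy, cx, r_out, r_in)
        # lumens persist: re-punch earlier cores the new ring painted over
        if (r_in > 0 && g > 1L) {
          for (j in seq_len(g - 1L)) {
            truth <- .paint_annulus(truth, centers[j, 1L], centers[j, 2L],
                                    r_in, r_in)
          }
        }
        epi_frac <- sum(truth == 2L) / sum(truth != 0L)
        if (epi_frac >= ef) break
      }
      if (abs(epi_frac - ef) > 0.05) {
        stop(sprintf(paste0("infeasible geometry: realized epithelium fraction",
                            " %.3f is more than 0.05 from target %.3f"),
                     epi_frac, ef), call. = FALSE)
      }
    }

    # compose colors from the palette, then perturb
    color_idx <- tone
    color_idx[truth == 0L] <- 1L
    color_idx[truth == 2L] <- 4L
    img <- array(0, c(h, w, 3L))
    for (ch in 1:3) img[, , ch] <- matrix(spec$palette[color_idx, ch], h, w)
    if (spec$color_noise_sd > 0) {
      img <- img + array(stats::rnorm(n_px * 3L, 0, spec$color_noise_sd),
                         c(h, w, 3L))
      img <- round(pmin(pmax(img, 0), 255))
    }
    list(image = img, truth = truth)
  })

  structure(list(image = out$image, truth = out$truth, spec = spec),
            class = "synthetic_micrograph")
}

#' Ground-truth epithelium percentage of a synthetic micrograph
#'
#' The epithelium percentage is defined as
#' `100 * epithelium area / (epithelium area + stroma area)`; lumen pixels do
#' not enter the denominator.
#'
#' @param m A `synthetic_micrograph`, or a bare integer label matrix with
#'   codes 0 = lumen, 1 = stroma, 2 = epithelium.
#' @return The epithelium percentage in `[0, 100]`.
#' @export
truth_epithelium_percentage <- function(m) {
  truth <- if (inherits(m, "synthetic_micrograph")) m$truth else m
  if (is.null(truth) || !all(truth %in% 0:2)) {
    stop("truth labels must use codes 0 (lumen), 1 (stroma), 2 (epithelium)",
         call. = FALSE)
  }
  n_epi <- sum(truth == 2L)
  n_str <- sum(truth == 1L)
  if (n_epi + n_str == 0L) {
    stop("degenerate input: no epithelium or stroma pixels", call. = FALSE)
  }
  100 * n_epi / (n_epi + n_str)
}

#' Ground-truth epithelium mask of a synthetic micrograph
#'
#' @param m A `synthetic_micrograph`.
#' @return A logical matrix, `TRUE` over epithelium pixels. Useful as the
#'   manual annotation mask when training on synthetic data.
#' @export
truth_epithelium_mask <- function(m) {
  stopifnot(inherits(m, "synthetic_micrograph"))
  m$truth == 2L
}

#' @export
print.synthetic_micrograph <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("synthetic H&E micrograph: %d x %d px (%.1f um/px)\n",
              d[2L], d[1L], x$spec$microns_per_pixel))
  fr <- tabulate(x$truth + 1L, 3L) / length(x$truth)
  cat(sprintf("  lumen %.1f%% | stroma %.1f%% | epithelium %.1f%% of pixels\n",
              100 * fr[1L], 100 * fr[2L], 100 * fr[3L]))
  cat(sprintf("  epithelium percentage (of tissue): %.2f%%\n",
              truth_epithelium_percentage(x)))
  invisible(x)
}
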