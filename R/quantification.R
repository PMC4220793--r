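# Epithelium quantification: convert classified grid cells into tissue-class
# areas and the epithelium percentage, per image and pooled per case.

#' Epithelium estimate for one image
#'
#' Applies the epithelium percentage formula
#' `100 * epithelial / (epithelial + stromal)` to classified grid-cell counts;
#' luminal cells never enter the denominator. A cell-area column in mm^2 is
#' provided as a convenience (0.0016 mm^2 per cell for a 20-px cell at
#' 2 um/px).
#'
#' @param labels Factor or character vector of per-cell tissue labels (as
#'   returned by [classify_cells()]); `NA` (excluded) cells are dropped.
#' @param image_id,case_id Optional identifiers carried into the result.
#' @param cell_area_mm2 Physical area of one grid cell in mm^2.
#' @return A one-row data frame of class `epithelium_estimate` with the cell
#'   counts, `epithelium_percent` and `epithelial_area_mm2`.
#' @export
estimate_image <- function(labels, image_id = NA_character_,
                           case_id = NA_character_, cell_area_mm2 = 0.0016) {
  labels <- factor(labels, levels = .tissue_classes)
  labels <- labels[!is.na(labels)]
  n <- tabulate(labels, 3L)
  if (n[1L] + n[2L] == 0L) {
    stop("degenerate input: no epithelial or stromal cells", call. = FALSE)
  }
  out <- data.frame(image_id = image_id, case_id = case_id,
                    n_epithelial = n[1L], n_stromal = n[2L], n_luminal = n[3L],
                    epithelium_percent = 100 * n[1L] / (n[1L] + n[2L]),
                    epithelial_area_mm2 = n[1L] * cell_area_mm2)
  class(out) <- c("epithelium_estimate", "data.frame")
  out
}

#' Pooled epithelium estimate for a case
#'
#' A case usually spans several micrograph tiles; the case-level estimate
#' pools the epithelial and stromal cell counts over all of its images and
#' applies the percentage formula to the pooled counts. This equals the
#' estimate over the whole face section and is *not* the mean of per-image
#' percentages (which would weight small tiles as much as large ones).
#'
#' @param estimates Per-image estimates, i.e. one or more
#'   [estimate_image()] rows (stacked with `rbind`).
#' @return A data frame with one row per case: pooled counts,
#'   `epithelium_percent` and `epithelium_fraction` in `[0, 1]`.
#' @export
estimate_case <- function(estimates) {
  if (is.null(estimates) || nrow(estimates) == 0L) {
    stop("empty case: no image estimates supplied", call. = FALSE)
  }
  case <- as.character(estimates$case_id)
  case[is.na(case)] <- "case"
  agg <- stats::aggregate(
    estimates[c("n_epithelial", "n_stromal", "n_luminal")],
    by = list(case_id = case), FUN = sum)
  denom <- agg$n_epithelial + agg$n_stromal
  if (any(denom == 0L)) {
    stop("degenerate input: a case has no epithelial or stromal cells",
         call. = FALSE)
  }
  agg$n_images <- as.vector(base::table(case)[agg$case_id])
  agg$epithelium_fraction <- agg$n_epithelial / denom
  agg$epithelium_percent <- 100 * agg$epithelium_fraction
  agg
}
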