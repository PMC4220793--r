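# Overlay rendering (predicted epithelium in green, false positives blue,
# false negatives magenta) and cluster scatter plots.

#' Overlay rendering options
#'
#' @param predicted,false_positive,false_negative Tint colors (any R color).
#' @param opacity Alpha of the tint in `(0, 1]` (default 0.4, translucent
#'   enough to keep the histology visible).
#' @param grid_outline Draw 1-px cell outlines in the tint color.
#' @return An object of class `overlay_spec`.
#' @export
overlay_spec <- function(predicted = "green", false_positive = "blue",
                         false_negative = "magenta", opacity = 0.4,
                         grid_outline = FALSE) {
  cols <- c(predicted = predicted, false_positive = false_positive,
            false_negative = false_negative)
  if (anyDuplicated(cols)) stop("overlay colors must be distinct", call. = FALSE)
  if (opacity <= 0 || opacity > 1) stop("`opacity` must be in (0, 1]",
                                        call. = FALSE)
  structure(list(colors = cols, opacity = opacity,
                 grid_outline = isTRUE(grid_outline)),
            class = "overlay_spec")
}

#' Render a classification overlay on a micrograph
#'
#' Tints predicted-epithelial grid cells green. When truth labels are given,
#' false-positive cells (predicted epithelial, truly non-epithelial) are
#' tinted blue and false-negative cells magenta instead; correctly
#' non-epithelial cells are left untouched.
#'
#' @param image RGB array (h x w x 3), 0--255 or 0--1 scale.
#' @param table The `grid_cell_table` the labels refer to (provides the grid
#'   geometry).
#' @param predicted Factor/character vector of predicted tissue labels, one
#'   per table row.
#' @param truth Optional vector of true tissue labels (same length).
#' @param spec An [overlay_spec()].
#' @return An RGB array (0--255) of the same dimensions as `image`.
#' @export
render_overlay <- function(image, table, predicted, truth = NULL,
                           spec = overlay_spec()) {
  stopifnot(inherits(table, "grid_cell_table"), inherits(spec, "overlay_spec"))
  img <- .image_to_unit(image) * 255
  if (!identical(dim(img)[1:2], attr(table, "img_dim"))) {
    stop("misaligned grids: image dimensions do not match the table's source image",
         call. = FALSE)
  }
  if (length(predicted) != nrow(table)) {
    stop("`predicted` must have one label per grid cell", call. = FALSE)
  }
  if (!is.null(truth) && length(truth) != nrow(table)) {
    stop("`truth` must have one label per grid cell", call. = FALSE)
  }
  cs <- attr(table, "cell_size")
  pred_epi <- !is.na(predicted) & predicted == "epithelial"
  tint <- rep(NA_character_, nrow(table))
  if (is.null(truth)) {
    tint[pred_epi] <- "predicted"
  } else {
    truth_epi <- !is.na(truth) & truth == "epithelial"
    tint[pred_epi & truth_epi] <- "predicted"
    tint[pred_epi & !truth_epi] <- "false_positive"
    tint[!pred_epi & truth_epi] <- "false_negative"
  }
  rgb255 <- grDevices::col2rgb(spec$colors)
  a <- spec$opacity
  for (i in which(!is.na(tint))) {
    rr <- ((table$row[i] - 1L) * cs + 1L):(table$row[i] * cs)
    cc <- ((table$col[i] - 1L) * cs + 1L):(table$col[i] * cs)
    col <- rgb255[, tint[i]]
    for (ch in 1:3) {
      img[rr, cc, ch] <- (1 - a) * img[rr, cc, ch] + a * col[ch]
    }
    if (spec$grid_outline) {
      for (ch in 1:3) {
        img[range(rr), cc, ch] <- col[ch]
        img[rr, range(cc), ch] <- col[ch]
      }
    }
  }
  round(img)
}

#' Scatter plot of grid cells in color-ratio space
#'
#' Draws the cells of a (marked or classified) grid-cell table as a 3-D
#' scatter in the space of three color ratios, epithelial cells in one color
#' and non-epithelial cells in another, and writes it to a PNG file.
#'
#' @param table A `grid_cell_table`.
#' @param file Output PNG path.
#' @param axes Three semantic ratio names.
#' @param labels Optional logical/character/factor vector saying which cells
#'   are epithelial; defaults to `epithelial_marked`, falling back to
#'   `tissue_class == "epithelial"`.
#' @param colors Length-2 colors for epithelial / non-epithelial points.
#' @param width,height Device size in pixels.
#' @return Invisibly, the data frame of plotted points.
#' @export
render_ratio_scatter <- function(table, file,
                                 axes = c("white", "dark_pink", "purple"),
                                 labels = NULL,
                                 colors = c("red", "blue"),
                                 width = 640, height = 640) {
  feats <- select_ratio_axes(table, axes)
  keep <- !table$excluded
  if (is.null(labels)) {
    labels <- if (!all(is.na(table$epithelial_marked))) {
      table$epithelial_marked
    } else if (!is.null(table$tissue_class)) {
      table$tissue_class == "epithelial"
    } else {
      stop("no epithelial labels available; pass `labels`", call. = FALSE)
    }
  }
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "epithelial"
  }
  df <- data.frame(feats[keep, , drop = FALSE],
                   epithelial = factor(ifelse(labels[keep], "epithelial",
                                              "non-epithelial")))
  names(df)[1:3] <- axes
  p <- lattice::cloud(
    stats::as.formula(sprintf("`%s` ~ `%s` * `%s`", axes[3L], axes[1L],
                              axes[2L])),
    data = df, groups = df$epithelial,
    col = colors, pch = 20, cex = 0.4,
    xlab = paste(axes[1L], "ratio"), ylab = paste(axes[2L], "ratio"),
    zlab = paste(axes[3L], "ratio"),
    auto.key = list(points = TRUE))
  grDevices::png(file, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(df)
}
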