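# Grid-cell featurization: tile a color-labeled micrograph into fixed-size
# square cells and compute per-cell color-area ratios. A 20 x 20 pixel cell at
# 2 um/px covers 0.04 x 0.04 mm^2 of tissue.

# cell id (row-major) of every pixel in the cropped h2 x w2 raster
.grid_cellid <- function(h2, w2, cell_size, cell_cols) {
  rowcell <- (seq_len(h2) - 1L) %/% cell_size
  colcell <- (seq_len(w2) - 1L) %/% cell_size
  outer(rowcell, colcell, function(a, b) a * cell_cols + b + 1L)
}

#' Tile a color label map into grid cells and compute color-area ratios
#'
#' The grid is anchored at the top-left pixel; partial cells at the right and
#' bottom borders are dropped so every retained cell has exactly
#' `cell_size^2` pixels and the ratio denominator is constant. The four color
#' ratios of each cell sum to 1 (closure), so only three are linearly
#' independent. Cells overlapping an exclusion mask by *any* pixel are flagged
#' `excluded`.
#'
#' @param labelmap A [assign_color_labels()] result (or a bare integer label
#'   matrix, in which case `semantic_order` must be given).
#' @param cell_size Cell edge in pixels (default 20).
#' @param exclusion_mask Optional logical matrix matching the full image;
#'   `TRUE` marks pixels (e.g. trimmed regions) whose cells must be excluded.
#' @param semantic_order Color names for the ratio columns when `labelmap` is
#'   a bare matrix.
#' @return A `grid_cell_table`: a data frame with one row per retained cell —
#'   `row`, `col` (1-based grid indices), `pixel_count`, one ratio column per
#'   color, `epithelial_marked` (`NA` until [mark_epithelial_cells()]) and
#'   `excluded` — carrying `cell_size`, `cell_rows`, `cell_cols` and
#'   `img_dim` attributes.
#' @export
tile_and_featurize <- function(labelmap, cell_size = 20L, exclusion_mask = NULL,
                               semantic_order = NULL) {
  if (inherits(labelmap, "color_label_map")) {
    labels <- labelmap$labels
    semantic_order <- labelmap$model$semantic_order
  } else {
    labels <- labelmap
    if (is.null(semantic_order)) {
      semantic_order <- .semantic_colors[seq_len(max(labels))]
    }
  }
  stopifnot(is.matrix(labels), cell_size >= 1L)
  n_colors <- length(semantic_order)
  h <- nrow(labels); w <- ncol(labels)
  cell_rows <- h %/% cell_size
  cell_cols <- w %/% cell_size
  if (cell_rows < 1L || cell_cols < 1L) {
    stop(sprintf("degenerate input: image (%d x %d) smaller than one %d-px cell",
                 h, w, cell_size), call. = FALSE)
  }
  h2 <- cell_rows * cell_size
  w2 <- cell_cols * cell_size
  lab <- labels[seq_len(h2), seq_len(w2), drop = FALSE]
  cellid <- .grid_cellid(h2, w2, cell_size, cell_cols)
  n_cells <- cell_rows * cell_cols

  counts <- vapply(seq_len(n_colors),
                   function(s) tabulate(cellid[lab == s], n_cells),
                   integer(n_cells))
  ratios <- counts / cell_size^2

  excluded <- rep(FALSE, n_cells)
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), c(h, w))) {
      stop("`exclusion_mask` dimensions must match the image", call. = FALSE)
    }
    ex <- exclusion_mask[seq_len(h2), seq_len(w2), drop = FALSE]
    excluded <- tabulate(cellid[ex], n_cells) > 0L
  }

  tab <- data.frame(row = rep(seq_len(cell_rows), each = cell_cols),
                    col = rep(seq_len(cell_cols), times = cell_rows),
                    pixel_count = cell_size^2L)
  tab[semantic_order] <- as.data.frame(ratios)
  tab$epithelial_marked <- NA
  tab$excluded <- excluded
  structure(tab,
            cell_size = as.integer(cell_size),
            cell_rows = cell_rows, cell_cols = cell_cols,
            img_dim = c(h, w), semantic_order = semantic_order,
            class = c("grid_cell_table", "data.frame"))
}

#' Mark grid cells as epithelial from a manual annotation mask
#'
#' A cell is marked epithelial when the fraction of its pixels inside the mask
#' reaches `cell_fraction_threshold` (>=, so exactly half coverage at the
#' default 0.5 marks the cell).
#'
#' @param table A [tile_and_featurize()] result.
#' @param epithelium_mask Logical matrix matching the full source image.
#' @param cell_fraction_threshold Minimum in-mask pixel fraction (default 0.5).
#' @return `table` with `epithelial_marked` filled in.
#' @export
mark_epithelial_cells <- function(table, epithelium_mask,
                                  cell_fraction_threshold = 0.5) {
  stopifnot(inherits(table, "grid_cell_table"))
  img_dim <- attr(table, "img_dim")
  if (!identical(dim(epithelium_mask), img_dim)) {
    stop(sprintf("mask dimensions (%d x %d) do not match the image (%d x %d)",
                 nrow(epithelium_mask), ncol(epithelium_mask),
                 img_dim[1L], img_dim[2L]), call. = FALSE)
  }
  cs <- attr(table, "cell_size")
  cell_rows <- attr(table, "cell_rows"); cell_cols <- attr(table, "cell_cols")
  h2 <- cell_rows * cs; w2 <- cell_cols * cs
  mk <- epithelium_mask[seq_len(h2), seq_len(w2), drop = FALSE]
  cellid <- .grid_cellid(h2, w2, cs, cell_cols)
  frac <- tabulate(cellid[mk], cell_rows * cell_cols) / cs^2
  table$epithelial_marked <- frac >= cell_fraction_threshold
  table
}

#' Project grid-cell ratios onto three chosen color axes
#'
#' The four color ratios are closed (they sum to 1), so any three of them
#' carry the full information; classification is performed in the space of
#' three chosen ratios.
#'
#' @param table A `grid_cell_table` (or any data frame with the ratio
#'   columns).
#' @param axes Three distinct semantic color names (default
#'   `c("white", "dark_pink", "purple")`).
#' @return An `n_cells` x 3 numeric matrix, columns in the order of `axes`.
#' @export
select_ratio_axes <- function(table, axes = c("white", "dark_pink", "purple")) {
  if (anyDuplicated(axes)) stop("`axes` must be distinct", call. = FALSE)
  missing_axes <- setdiff(axes, names(table))
  if (length(missing_axes)) {
    stop(sprintf("unknown ratio axis: %s", paste(missing_axes, collapse = ", ")),
         call. = FALSE)
  }
  as.matrix(as.data.frame(table)[, axes, drop = FALSE])
}

#' Write / read a grid-cell table as CSV
#'
#' Grid geometry (cell size, source image dimensions) travels as extra
#' columns so the attributes survive the round trip.
#'
#' @param table A `grid_cell_table`.
#' @param path File path.
#' @return `write_grid_table` returns `path` invisibly; `read_grid_table`
#'   returns a `grid_cell_table`.
#' @export
write_grid_table <- function(table, path) {
  stopifnot(inherits(table, "grid_cell_table"))
  out <- as.data.frame(table)
  out$cell_size <- attr(table, "cell_size")
  out$img_rows <- attr(table, "img_dim")[1L]
  out$img_cols <- attr(table, "img_dim")[2L]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_table
#' @export
read_grid_table <- function(path) {
  df <- utils::read.csv(path)
  cs <- df$cell_size[1L]
  img_dim <- c(df$img_rows[1L], df$img_cols[1L])
  df$cell_size <- df$img_rows <- df$img_cols <- NULL
  ratio_cols <- setdiff(names(df), c("row", "col", "pixel_count",
                                     "epithelial_marked", "excluded",
                                     "tissue_class"))
  structure(df, cell_size = as.integer(cs),
            cell_rows = max(df$row), cell_cols = max(df$col),
            img_dim = as.integer(img_dim), semantic_order = ratio_cols,
            class = c("grid_cell_table", "data.frame"))
}
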