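# Normalization of per-case assay concentrations by epithelium fraction,
# fold changes, rank-based group comparison, and agreement between the
# computer-aided and pathologist epithelium estimates.

#' Read per-case assay measurements from CSV
#'
#' Expected columns: `case_id`, `group` (two labels, e.g. normal/tumor),
#' `analyte`, `concentration` (ng per mg total protein; the alias
#' `concentration_ng_per_mg` is accepted), and optionally
#' `epi_fraction_computer` and `epi_fraction_pathologist` in `(0, 1]`.
#'
#' @param path CSV file path.
#' @return A data frame of measurements.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("concentration_ng_per_mg" %in% names(df) &&
      !"concentration" %in% names(df)) {
    df$concentration <- df$concentration_ng_per_mg
  }
  required <- c("case_id", "group", "analyte", "concentration")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("measurements file lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Normalize assay concentrations by epithelium fraction
#'
#' Divides each case's concentration by its epithelium *fraction* (percent /
#' 100), so a specimen that is 25% epithelium has its epithelial-protein
#' reading scaled up fourfold. Units become
#' ng per mg total protein per epithelium fraction. The raw concentration
#' column is retained.
#'
#' @param measurements Data frame with `concentration` and an
#'   `epi_fraction_computer` / `epi_fraction_pathologist` column.
#' @param which_fraction Which epithelium estimate to normalize by.
#' @return `measurements` with a `normalized_value` column added.
#' @export
#' @examples
#' df <- data.frame(case_id = c("a", "b"), group = c("normal", "tumor"),
#'                  analyte = "EpCAM", concentration = c(10, 20),
#'                  epi_fraction_computer = c(0.25, 0.5))
#' normalize_by_epithelium(df)$normalized_value # 40 40
normalize_by_epithelium <- function(measurements,
                                    which_fraction = c("computer",
                                                       "pathologist")) {
  which_fraction <- match.arg(which_fraction)
  col <- paste0("epi_fraction_", which_fraction)
  if (!col %in% names(measurements)) {
    stop(sprintf("measurements lack column `%s`", col), call. = FALSE)
  }
  f <- measurements[[col]]
  bad <- is.na(f) | f <= 0 | f > 1
  if (any(bad)) {
    stop(sprintf("epithelium fraction missing or outside (0, 1] for case(s): %s",
                 paste(unique(measurements$case_id[bad]), collapse = ", ")),
         call. = FALSE)
  }
  measurements$normalized_value <- measurements$concentration / f
  measurements
}

.two_group_values <- function(measurements, analyte, value, groups) {
  sub <- measurements[measurements$analyte == analyte, , drop = FALSE]
  if (!value %in% names(sub)) {
    stop(sprintf("value column `%s` not found (run normalize_by_epithelium()?)",
                 value), call. = FALSE)
  }
  out <- lapply(groups, function(g) sub[[value]][sub$group == g])
  names(out) <- groups
  if (any(!lengths(out))) {
    stop(sprintf("empty group for analyte %s: %s", analyte,
                 paste(groups[!lengths(out)], collapse = ", ")), call. = FALSE)
  }
  out
}

#' Fold change between groups
#'
#' Arithmetic mean of the second (tumor) group divided by the arithmetic mean
#' of the first (normal) group, reported to two decimals.
#'
#' @param measurements Measurements data frame.
#' @param analyte Analyte name (e.g. `"EpCAM"`).
#' @param value Column to compare: raw `"concentration"` (default) or
#'   `"normalized_value"`.
#' @param groups Reference and comparison group labels, in that order.
#' @return The fold change, rounded to 2 decimals.
#' @export
fold_change <- function(measurements, analyte, value = "concentration",
                        groups = c("normal", "tumor")) {
  v <- .two_group_values(measurements, analyte, value, groups)
  round(mean(v[[2L]]) / mean(v[[1L]]), 2L)
}

#' Compare an analyte between two groups
#'
#' Two-sided unpaired Wilcoxon rank-sum (Mann-Whitney) test by default: exact
#' when both groups have fewer than 50 observations and the data are tie-free,
#' otherwise the tie-corrected normal approximation with continuity
#' correction. A paired signed-rank variant is available for designs that
#' warrant it. Constant pooled data yield a degenerate-data warning and
#' p = 1.
#'
#' @inheritParams fold_change
#' @param test `"rank_sum"` (unpaired, default) or `"signed_rank"` (paired).
#' @return An object of class `group_comparison`: per-group n/mean/sd, the
#'   fold change, test name, statistic and two-sided p-value.
#' @export
compare_groups <- function(measurements, analyte, value = "concentration",
                           groups = c("normal", "tumor"),
                           test = c("rank_sum", "signed_rank")) {
  test <- match.arg(test)
  v <- .two_group_values(measurements, analyte, value, groups)
  x <- v[[1L]]; y <- v[[2L]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  stats_df <- data.frame(group = groups,
                         n = c(length(x), length(y)),
                         mean = c(mean(x), mean(y)),
                         sd = c(stats::sd(x), stats::sd(y)))
  if (length(unique(c(x, y))) == 1L) {
    warning("degenerate data: all values identical; p set to 1", call. = FALSE)
    w <- NA_real_
    p <- 1
    test_name <- test
  } else if (test == "signed_rank") {
    if (length(x) != length(y)) {
      stop("signed-rank test requires paired groups of equal size",
           call. = FALSE)
    }
    ht <- stats::wilcox.test(y, x, paired = TRUE, alternative = "two.sided",
                             exact = !any(duplicated(abs(y - x))) &&
                               all(y != x))
    w <- unname(ht$statistic); p <- ht$p.value
    test_name <- "Wilcoxon signed-rank (paired, two-sided)"
  } else {
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- !ties && length(x) < 50L && length(y) < 50L
    ht <- suppressWarnings(
      stats::wilcox.test(y, x, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    w <- unname(ht$statistic); p <- ht$p.value
    test_name <- "Wilcoxon rank-sum / Mann-Whitney (unpaired, two-sided)"
  }
  structure(list(analyte = analyte, value = value, group_stats = stats_df,
                 fold_change = round(mean(y) / mean(x), 2L),
                 statistic = w, p_value = p, test_name = test_name),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$analyte, x$value))
  for (i in seq_len(nrow(x$group_stats))) {
    cat(sprintf("  %-8s n = %2d  %.2f +/- %.2f\n",
                x$group_stats$group[i], x$group_stats$n[i],
                x$group_stats$mean[i], x$group_stats$sd[i]))
  }
  cat(sprintf("  fold change %.2f; %s p = %.4g\n",
              x$fold_change, x$test_name, x$p_value))
  invisible(x)
}

#' Agreement between computer-aided and pathologist epithelium estimates
#'
#' Pearson correlation on paired case-level epithelium fractions, with the
#' two-sided p-value from the t transform of r.
#'
#' @param computer,pathologist Paired numeric vectors of case-level epithelium
#'   fractions (or percentages; only linearity matters).
#' @return An object of class `method_comparison` with `r`, `p_value` and `n`.
#' @export
compare_methods <- function(computer, pathologist) {
  ok <- stats::complete.cases(computer, pathologist)
  x <- computer[ok]; y <- pathologist[ok]
  if (length(x) < 3L) stop("need at least 3 paired cases", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the estimates; correlation undefined",
         call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ht$estimate), p_value = ht$p.value,
                 n = length(x)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f over %d paired cases (two-sided p = %.3g)\n",
              x$r, x$n, x$p_value))
  invisible(x)
}
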