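# Small fixtures built in code; everything is seeded and cheap.

small_spec <- function(ef = 0.35, seed = 7, noise = 0, ...) {
  synthetic_spec(width_px = 120L, height_px = 120L,
                 target_epithelium_fraction = ef, lumen_fraction = 0.08,
                 color_noise_sd = noise, gland_count = 4L, seed = seed, ...)
}

small_micrograph <- function(...) generate_micrograph(small_spec(...))

# a marked, featurized grid table for a small synthetic image
small_marked_table <- function(ef = 0.35, seed = 7, noise = 0, n_init = 3) {
  m <- small_micrograph(ef = ef, seed = seed, noise = noise)
  model <- fit_color_model(m$image, seed = seed, n_init = n_init)
  tab <- tile_and_featurize(assign_color_labels(m$image, model))
  mark_epithelial_cells(tab, truth_epithelium_mask(m))
}

# grid-aligned cells that are (nearly) pure colors: exactly separable classes
block_aligned_table <- function(n_epi = 40, n_str = 50, n_lum = 10, seed = 1,
                                jitter = 0) {
  ratios <- rbind(
    matrix(rep(c(0.02, 0.03, 0.05, 0.90), n_epi), ncol = 4, byrow = TRUE),
    matrix(rep(c(0.05, 0.55, 0.35, 0.05), n_str), ncol = 4, byrow = TRUE),
    matrix(rep(c(0.90, 0.04, 0.03, 0.03), n_lum), ncol = 4, byrow = TRUE))
  if (jitter > 0) {
    noise <- epiquant:::.with_seed(seed, matrix(stats::rnorm(length(ratios),
                                                             0, jitter),
                                                nrow(ratios)))
    ratios <- pmax(ratios + noise, 0)
    ratios <- ratios / rowSums(ratios)
  }
  ratio_table(t(ratios), marked = rep(c(TRUE, FALSE, FALSE),
                                      c(n_epi, n_str, n_lum)))
}

# a bare ratio table with hand-set ratios (white, light_pink, dark_pink, purple)
ratio_table <- function(ratios, marked = NA, excluded = FALSE) {
  ratios <- matrix(ratios, ncol = 4L, byrow = TRUE)
  tab <- data.frame(row = seq_len(nrow(ratios)), col = 1L,
                    pixel_count = 400L)
  tab[c("white", "light_pink", "dark_pink", "purple")] <- as.data.frame(ratios)
  tab$epithelial_marked <- marked
  tab$excluded <- excluded
  structure(tab, cell_size = 20L, cell_rows = nrow(ratios), cell_cols = 1L,
            img_dim = c(20L * nrow(ratios), 20L),
            semantic_order = c("white", "light_pink", "dark_pink", "purple"),
            class = c("grid_cell_table", "data.frame"))
}

# measurements table with exact group means/sds via standardized draws
moment_matched_groups <- function(n1, mean1, sd1, n2, mean2, sd2, analyte,
                                  seed = 1) {
  standardize <- function(n, mu, s) {
    z <- epiquant:::.with_seed(seed + n, stats::rnorm(n))
    mu + s * (z - mean(z)) / stats::sd(z)
  }
  data.frame(case_id = sprintf("%s_%02d", analyte, seq_len(n1 + n2)),
             group = rep(c("normal", "tumor"), c(n1, n2)),
             analyte = analyte,
             concentration = c(standardize(n1, mean1, sd1),
                               standardize(n2, mean2, sd2)))
}
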