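test_that("the white-content lumen rule is strict and overrides marks", {
  tab <- ratio_table(c(0.71, 0.1, 0.1, 0.09,
                       0.70, 0.1, 0.1, 0.10,
                       0.10, 0.4, 0.4, 0.10),
                     marked = c(FALSE, TRUE, FALSE))
  lab <- derive_training_labels(tab)$tissue_class
  expect_identical(as.character(lab), c("luminal", "epithelial", "stromal"))

  expect_error(derive_training_labels(ratio_table(c(0.1, 0.2, 0.3, 0.4))),
               "marks missing")
})

test_that("training lands on class means for separated blobs and tiny inputs", {
  tab <- block_aligned_table(jitter = 0.02)
  labeled <- derive_training_labels(tab)
  model <- train_class_model(labeled, seed = 1)
  feats <- select_ratio_axes(labeled)
  for (g in c("epithelial", "stromal", "luminal")) {
    expect_equal(unname(model$centroids[g, ]),
                 unname(colMeans(feats[labeled$tissue_class == g, ,
                                       drop = FALSE])),
                 tolerance = 1e-9)
  }
  # Lloyd refinement makes no update when classes are separated blobs
  refined <- train_class_model(labeled, seed = 1, centroids_only = TRUE)
  expect_equal(model$centroids, refined$centroids, tolerance = 1e-9)

  # single cell per class: centroids equal those cells
  tiny <- ratio_table(c(0.05, 0.05, 0.05, 0.85,
                        0.05, 0.50, 0.40, 0.05,
                        0.90, 0.05, 0.03, 0.02),
                      marked = c(TRUE, FALSE, FALSE))
  tm <- train_class_model(derive_training_labels(tiny))
  expect_equal(unname(tm$centroids["epithelial", ]), c(0.05, 0.05, 0.85))
  expect_equal(unname(tm$centroids["luminal", ]), c(0.90, 0.03, 0.02))

  # duplicating all cells changes nothing (means are scale-invariant)
  doubled <- tiny[rep(seq_len(nrow(tiny)), 2L), ]
  expect_equal(train_class_model(derive_training_labels(doubled))$centroids,
               tm$centroids)

  # an empty class errors by name
  no_lumen <- ratio_table(c(0.05, 0.05, 0.05, 0.85,
                            0.05, 0.50, 0.40, 0.05),
                          marked = c(TRUE, FALSE))
  expect_error(train_class_model(derive_training_labels(no_lumen)),
               "empty training class: luminal")
})

test_that("classification is nearest-centroid with the documented tie order", {
  model <- structure(list(
    centroids = matrix(c(0, 0, 1,
                         0, 1, 0,
                         1, 0, 0), 3, 3, byrow = TRUE,
                       dimnames = list(c("epithelial", "stromal", "luminal"),
                                       c("white", "dark_pink", "purple"))),
    axes = c("white", "dark_pink", "purple"),
    white_lumen_threshold = 0.7, seed = 1L),
    class = "tissue_class_model")

  # cell exactly at the epithelial centroid
  at_centroid <- ratio_table(c(0, 0, 0, 1))
  expect_identical(as.character(classify_cells(at_centroid, model)),
                   "epithelial")
  # equidistant epithelial/stromal: epithelial wins the tie
  tie <- ratio_table(c(0, 0, 0.5, 0.5))
  expect_identical(as.character(classify_cells(tie, model)), "epithelial")
  # excluded cells get NA
  excl <- ratio_table(c(0, 0, 0, 1), excluded = TRUE)
  expect_true(is.na(classify_cells(excl, model)))
  # axis mismatch errors
  bad <- ratio_table(c(0, 0, 0, 1))
  names(bad)[names(bad) == "dark_pink"] <- "rose"
  expect_error(classify_cells(bad, model), "axis mismatch")

  # brute-force oracle on 200 random cells: identical labels
  feats <- epiquant:::.with_seed(5, matrix(runif(600), 200, 3))
  tab <- ratio_table(t(cbind(feats[, 1], 0, feats[, 2], feats[, 3])))
  pred <- classify_cells(tab, model)
  brute <- character(200)
  for (i in 1:200) {
    d <- colSums((t(model$centroids) - feats[i, ])^2)
    brute[i] <- rownames(model$centroids)[which(d == min(d))[1L]]
  }
  expect_identical(as.character(pred), brute)

  # idempotent and deterministic given a model
  expect_identical(classify_cells(tab, model), pred)
})

test_that("cross-validation is perfect on exactly separable cell tables", {
  tabs <- lapply(1:4, function(s) block_aligned_table(
    n_epi = 20 + 10 * s, n_str = 60 - 10 * s, n_lum = 12, jitter = 0.02,
    seed = s))
  cv <- cross_validate(tabs, seed = 3)
  expect_equal(cv$accuracy_mean, 100)
  expect_equal(cv$false_positive_mean, 0)
  expect_equal(cv$false_negative_mean, 0)
  # predicted counts == marked counts per image => perfect area correlation
  expect_equal(cv$area_r2, 1)
})

test_that("accuracy, FP and FN share a denominator and close to 100 exactly", {
  tabs <- lapply(1:3, function(s) block_aligned_table(jitter = 0.25, seed = s))
  cv <- suppressWarnings(cross_validate(tabs, seed = 9))
  closure <- cv$per_image$accuracy + cv$per_image$false_positive +
    cv$per_image$false_negative
  expect_equal(closure, rep(100, nrow(cv$per_image)), tolerance = 1e-12)
})

test_that("a coin-flip classifier scores near 50% on a balanced set", {
  # balanced two-class table; replace model predictions by a seeded fair coin
  n <- 400
  truth <- rep(c(TRUE, FALSE), n / 2)
  flips <- epiquant:::.with_seed(11, sample(c(TRUE, FALSE), n, TRUE))
  acc <- mean(flips == truth)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n))
})

test_that("tissue class models round-trip through YAML", {
  tab <- derive_training_labels(block_aligned_table(jitter = 0.02))
  model <- train_class_model(tab)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_class_model(model, path)
  back <- read_class_model(path)
  expect_equal(back$centroids, model$centroids)
  expect_identical(classify_cells(tab, back), classify_cells(tab, model))
})

test_that("estimation error shrinks as color noise shrinks", {
  mae_at <- function(noise) {
    ms <- lapply(1:3, function(i) generate_micrograph(synthetic_spec(
      width_px = 200, height_px = 200, target_epithelium_fraction = 0.2 * i,
      lumen_fraction = 0.08, gland_count = max(2L, 3L * i),
      color_noise_sd = noise, seed = 40 + i)))
    res <- suppressWarnings(epithelium_pipeline(ms, training_index = 2,
                                                seed = 5, n_init = 4))
    mean(abs(res$estimates$epithelium_percent - res$estimates$truth_percent))
  }
  # wide noise spread so the trend dominates simulation error
  expect_lt(mae_at(4), mae_at(60) + 1)
})
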