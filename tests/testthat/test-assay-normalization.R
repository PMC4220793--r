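test_that("normalization divides by the epithelium fraction and guards its domain", {
  df <- data.frame(case_id = c("a", "b", "c"), group = "tumor",
                   analyte = "EpCAM", concentration = c(10, 10, 8),
                   epi_fraction_computer = c(1, 0.25, 0.5),
                   epi_fraction_pathologist = c(0.5, 0.5, 0.25))
  out <- normalize_by_epithelium(df)
  expect_equal(out$normalized_value, c(10, 40, 16))
  expect_true(all(out$normalized_value >= out$concentration))
  expect_equal(out$concentration, df$concentration) # original retained

  path <- normalize_by_epithelium(df, "pathologist")
  expect_equal(path$normalized_value, c(20, 20, 32))

  df$epi_fraction_computer[2] <- 0
  expect_error(normalize_by_epithelium(df), "case\\(s\\): b")
  df$epi_fraction_computer[2] <- 1.2
  expect_error(normalize_by_epithelium(df), "b")
  expect_error(normalize_by_epithelium(df[, 1:4]), "epi_fraction_computer")
})

test_that("fold change is the ratio of group means, to two decimals", {
  epcam <- moment_matched_groups(8, 9.39, 4.22, 36, 44.61, 23.40, "EpCAM")
  ctsl <- moment_matched_groups(8, 6.30, 2.06, 36, 11.83, 4.56, "CTSL")
  both <- rbind(epcam, ctsl)
  expect_equal(fold_change(both, "EpCAM"), 4.75)
  expect_equal(fold_change(both, "CTSL"), 1.88)

  same <- data.frame(case_id = 1:6, group = rep(c("normal", "tumor"), 3),
                     analyte = "x", concentration = rep(c(2, 5), 3))
  same$concentration <- 3
  expect_equal(fold_change(same, "x"), 1)
  expect_error(fold_change(same[same$group == "tumor", ], "x"), "empty group")
})

test_that("normalization shifts fold changes by the predictable fraction ratio", {
  tab <- moment_matched_groups(8, 10, 3, 36, 30, 9, "prot")
  # constant fraction: fold unchanged
  tab$epi_fraction_computer <- 0.5
  expect_equal(fold_change(normalize_by_epithelium(tab), "prot",
                           value = "normalized_value"),
               fold_change(tab, "prot"))
  # group-dependent fractions scale the fold by f_normal / f_tumor
  tab$epi_fraction_computer <- ifelse(tab$group == "normal", 0.25, 0.5)
  fold_raw <- mean(tab$concentration[tab$group == "tumor"]) /
    mean(tab$concentration[tab$group == "normal"])
  expect_equal(fold_change(normalize_by_epithelium(tab), "prot",
                           value = "normalized_value"),
               round(fold_raw * 0.25 / 0.5, 2))
})

test_that("group comparison is a two-sided unpaired rank test with sane edge cases", {
  df <- moment_matched_groups(8, 10, 2, 36, 14, 3, "p1", seed = 4)
  cmp <- compare_groups(df, "p1")
  expect_s3_class(cmp, "group_comparison")
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
  expect_match(cmp$test_name, "rank-sum")

  # label swap leaves the two-sided p unchanged
  swapped <- df
  swapped$group <- ifelse(df$group == "normal", "tumor", "normal")
  expect_equal(compare_groups(swapped, "p1")$p_value, cmp$p_value)

  # invariant under strictly monotone transforms of the values
  tdf <- df
  tdf$concentration <- exp(df$concentration / 10)
  expect_equal(compare_groups(tdf, "p1")$p_value, cmp$p_value)

  # completely separated groups at the study sizes reach the exact minimum
  sep <- data.frame(case_id = 1:44, group = rep(c("normal", "tumor"), c(8, 36)),
                    analyte = "p2",
                    concentration = c(seq(1, 2, length.out = 8),
                                      seq(10, 20, length.out = 36)))
  pmin_exact <- 2 / choose(44, 8) # two-sided, all tumor > all normal
  expect_equal(compare_groups(sep, "p2")$p_value, pmin_exact, tolerance = 1e-12)

  # constant data: degenerate warning and p = 1
  flat <- data.frame(case_id = 1:8, group = rep(c("normal", "tumor"), 4),
                     analyte = "p3", concentration = 5)
  expect_warning(res <- compare_groups(flat, "p3"), "degenerate")
  expect_equal(res$p_value, 1)
})

test_that("rank-sum type-I error is calibrated at the study's group sizes", {
  n_sim <- 400
  alpha <- 0.05
  rejections <- epiquant:::.with_seed(123, {
    vapply(seq_len(n_sim), function(i) {
      df <- data.frame(case_id = 1:44,
                       group = rep(c("normal", "tumor"), c(8, 36)),
                       analyte = "null", concentration = stats::rnorm(44))
      compare_groups(df, "null")$p_value <= alpha
    }, logical(1))
  })
  rate <- mean(rejections)
  # binomial 3-sigma band around the nominal level
  expect_lt(abs(rate - alpha), 3 * sqrt(alpha * (1 - alpha) / n_sim) + 0.005)
})

test_that("method agreement uses Pearson r with a t-based p", {
  x <- seq(0.1, 0.9, length.out = 10)
  expect_equal(compare_methods(x, x)$r, 1)
  expect_equal(compare_methods(x, 1 - x)$r, -1)

  sim <- epiquant:::.with_seed(77, {
    z <- stats::rnorm(500)
    cbind(z, 0.7 * z + sqrt(1 - 0.49) * stats::rnorm(500))
  })
  est <- compare_methods(sim[, 1], sim[, 2])
  expect_lt(abs(est$r - 0.7), 0.06)
  expect_lt(est$p_value, 1e-10)

  expect_error(compare_methods(rep(0.5, 5), x[1:5]), "zero variance")
  expect_error(compare_methods(x[1:2], x[1:2]), "at least 3")
})

test_that("measurements round-trip through CSV with the documented columns", {
  df <- moment_matched_groups(4, 10, 2, 6, 20, 5, "EpCAM")
  df$epi_fraction_computer <- seq(0.2, 0.65, length.out = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  back <- read_measurements(path)
  expect_equal(back$concentration, df$concentration)

  # alias column accepted
  df2 <- df
  names(df2)[names(df2) == "concentration"] <- "concentration_ng_per_mg"
  utils::write.csv(df2, path, row.names = FALSE)
  expect_equal(read_measurements(path)$concentration, df$concentration)

  utils::write.csv(df[, c("case_id", "group")], path, row.names = FALSE)
  expect_error(read_measurements(path), "lacks column")
})
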