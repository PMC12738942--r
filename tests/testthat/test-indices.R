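test_that("chromatic coordinates normalize by the channel sum", {
  expect_equal(unlist(normalize_rgb(100, 100, 100)),
               c(r_norm = 1 / 3, g_norm = 1 / 3, b_norm = 1 / 3))
  expect_equal(unlist(normalize_rgb(50, 100, 50)),
               c(r_norm = 0.25, g_norm = 0.50, b_norm = 0.25))
  zero <- normalize_rgb(0, 0, 0)
  expect_true(all(is.na(unlist(zero))))
})

test_that("registry holds 4 visible, 6 multispectral, 14 purpose-built", {
  reg <- index_registry()
  expect_equal(nrow(reg), 24)
  expect_equal(unname(table(reg$family)[c("visible", "multispectral",
                                          "self")]),
               c(4L, 6L, 14L), ignore_attr = TRUE)
  expect_false(anyDuplicated(reg$name) > 0)
})

test_that("every index matches its hand-evaluated value on fixed bands", {
  # values computed by hand from the formulas at
  # RGB = (120, 150, 90) -> chromatic (1/3, 5/12, 1/4);
  # G/R/RE/NIR reflectance = 0.12 / 0.10 / 0.20 / 0.40
  s <- fixed_sample()
  expected <- c(
    ExG = 0.25, VARI = 1 / 6, ExGR = 0.2, RGBVI = 13 / 37,
    NDVI = 0.6, GNDVI = 0.28 / 0.52, SAVI = 0.45,
    MSAVI = (1.8 - sqrt(0.84)) / 2, NDRE = 1 / 3, EVI2 = 0.75 / 1.64,
    idx1 = 5 / 3, idx2 = 1.25, idx3 = 2, idx4 = 4, idx5 = 0.28 / 0.52,
    idx6 = 1 / 3, idx7 = 1 / 9, idx8 = 25 / 3, idx9 = 0.72,
    idx10 = 0.02 / 0.048, idx11 = 1 / 3, idx12 = 5 / 12, idx13 = 0.25,
    idx14 = 1 / 11
  )
  for (nm in names(expected)) {
    expect_equal(compute_index(nm, s), unname(expected[nm]),
                 tolerance = 1e-12, label = nm)
  }
})

test_that("degenerate inputs yield undefined markers, never silent zeros", {
  s <- fixed_sample()
  s$NIR_MS <- 0.3
  s$R_MS <- 0.3
  expect_equal(compute_index("NDVI", s), 0) # symmetric numerator
  eq <- data.frame(R_RGB = 80, G_RGB = 80, B_RGB = 80,
                   G_MS = 0.1, R_MS = 0.1, RE_MS = 0.1, NIR_MS = 0.1)
  expect_equal(compute_index("ExG", eq), 0)
  zero_den <- fixed_sample()
  zero_den$NIR_MS <- 0
  zero_den$R_MS <- 0
  expect_true(is.na(compute_index("NDVI", zero_den)))
  expect_error(compute_index("nope", fixed_sample()), "unknown index")
  expect_error(compute_index("NDVI", data.frame(R_RGB = 1)), "missing band")
})

test_that("SAVI follows the soil-adjusted formula for any L", {
  s <- fixed_sample()
  s$NIR_MS <- 0.6
  s$R_MS <- 0.2
  expect_equal(compute_index("SAVI", s, savi_L = 0.5),
               1.5 * 0.4 / 1.3, tolerance = 1e-12)
  expect_equal(compute_index("SAVI", s, savi_L = 0),
               compute_index("NDVI", s), tolerance = 1e-12)
})

test_that("feature matrix has registry order, carried labels, NA policy", {
  df <- generate_samples(small_scenario(n_per_class = 10, seed = 2))
  fm <- build_feature_matrix(df)
  expect_equal(dim(fm$values), c(40, 24))
  expect_equal(colnames(fm$values), index_registry()$name)
  expect_equal(as.character(fm$labels), as.character(df$label))

  one <- build_feature_matrix(fixed_sample(), indices = "NDVI")
  expect_equal(dim(one$values), c(1, 1))

  # zero RGB sum invalidates chromatic-coordinate indices only
  bad <- fixed_sample()
  bad$R_RGB <- bad$G_RGB <- bad$B_RGB <- 0
  both <- build_feature_matrix(rbind(fixed_sample(), bad))
  reg <- index_registry()
  needs_rgb <- reg$name[reg$source %in% c("rgb", "mixed")]
  ms_only <- setdiff(reg$name, needs_rgb)
  expect_true(all(is.na(both$values[2, needs_rgb])))
  expect_true(all(is.finite(both$values[2, ms_only])))
  expect_true(all(is.finite(both$values[1, ])))
  expect_error(build_feature_matrix(df, indices = character(0)), "empty")
})

test_that("index-set selections follow the registry source tags", {
  expect_equal(ncol(build_feature_matrix(fixed_sample(),
                                         indices = "visible")$values), 9)
  expect_equal(colnames(build_feature_matrix(fixed_sample(),
                                             indices = "visible")$values),
               c("ExG", "VARI", "ExGR", "RGBVI",
                 "idx1", "idx2", "idx11", "idx12", "idx13"))
  expect_equal(ncol(build_feature_matrix(fixed_sample(),
                                         indices = "new")$values), 14)
  expect_equal(ncol(build_feature_matrix(fixed_sample(),
                                         indices = "rgb_multi")$values), 10)
})

test_that("normalized-difference indices stay in [-1, 1] on valid bands", {
  df <- random_bands(400, seed = 11)
  fm <- build_feature_matrix(df)
  nd_idx <- c("NDVI", "GNDVI", "NDRE", "idx5", "idx6", "idx7", "idx14",
              "RGBVI")
  vals <- fm$values[, nd_idx]
  expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12, na.rm = TRUE))
  # chromatic coordinates sum to one for every valid sample
  cc <- normalize_rgb(df$R_RGB, df$G_RGB, df$B_RGB)
  expect_true(all(abs(rowSums(cc) - 1) < 1e-9))
})

test_that("chromatic-coordinate indices are brightness-scale invariant", {
  df <- random_bands(50, seed = 13)
  fm1 <- build_feature_matrix(df)
  df2 <- df
  df2[c("R_RGB", "G_RGB", "B_RGB")] <- df[c("R_RGB", "G_RGB", "B_RGB")] * 3.7
  fm2 <- build_feature_matrix(df2)
  reg <- index_registry()
  rgb_based <- reg$name[reg$source %in% c("rgb", "mixed")]
  expect_equal(fm1$values[, rgb_based], fm2$values[, rgb_based],
               tolerance = 1e-9)
  # idx11/12/13 are exactly the chromatic coordinates
  cc <- normalize_rgb(df$R_RGB, df$G_RGB, df$B_RGB)
  expect_equal(fm1$values[, "idx11"], cc$r_norm, ignore_attr = TRUE)
  expect_equal(fm1$values[, "idx12"], cc$g_norm, ignore_attr = TRUE)
  expect_equal(fm1$values[, "idx13"], cc$b_norm, ignore_attr = TRUE)
})

test_that("idx14 scaled mode varies with brightness, literal does not", {
  a <- fixed_sample()
  b <- fixed_sample()
  b[c("R_RGB", "G_RGB", "B_RGB")] <- b[c("R_RGB", "G_RGB", "B_RGB")] / 2
  expect_equal(compute_index("idx14", a), compute_index("idx14", b))
  expect_false(isTRUE(all.equal(
    compute_index("idx14", a, idx14_mode = "scaled"),
    compute_index("idx14", b, idx14_mode = "scaled")
  )))
})
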